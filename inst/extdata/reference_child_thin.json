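{"kind":"thin","rest_length_m":0.63749999999999996,"terms":[{"a_N":63.674582438336984,"b_per_pct":-0.098194152546543748,"c_rad":5.5484528953624892},{"a_N":61.447526660758527,"b_per_pct":0.099157456565375932,"c_rad":0.67831595203416539},{"a_N":92.375364597501118,"b_per_pct":0.016511776418752986,"c_rad":0.038765334263781148}],"r_squared":0.99999076350952554}
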