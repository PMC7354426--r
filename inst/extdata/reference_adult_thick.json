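{"kind":"thick","rest_length_m":0.61750000000000005,"terms":[{"a_N":197.06317247963455,"b_per_pct":-0.025020392969728338,"c_rad":-1.5961387020946711},{"a_N":-63.186775321179681,"b_per_pct":0.036975164885715485,"c_rad":3.8192794244334407},{"a_N":336.30863943299374,"b_per_pct":0.0055335368040301787,"c_rad":2.6556556809987164}],"r_squared":0.99999429729090317}
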