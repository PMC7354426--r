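# Child stabilisation, symmetric suspension: 12 kg subject, four thin
# cords stretched 100 mm, all at a 10-degree COG-level angle. Calibrated
# reference characteristic; approx. 16% unweighting with equal left and
# right foot forces.
subject:
  mass_kg: 12
  height_m: 0.88
  cog_height_m: 0.5104
  age_class: child
cords:
- characteristic: reference_child_thin
  cog_level_angle_deg: 10
  elongation_mm: 100
  azimuth_deg: 45
- characteristic: reference_child_thin
  cog_level_angle_deg: 10
  elongation_mm: 100
  azimuth_deg: 135
- characteristic: reference_child_thin
  cog_level_angle_deg: 10
  elongation_mm: 100
  azimuth_deg: 225
- characteristic: reference_child_thin
  cog_level_angle_deg: 10
  elongation_mm: 100
  azimuth_deg: 315
stance:
  left_foot_m: [0.0, 0.1, 0.0]
  right_foot_m: [0.0, -0.1, 0.0]
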