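# Adult verticalization, symmetric suspension: 75 kg subject, four thick
# cords stretched 250 mm, all at a 45-degree COG-level angle. Calibrated
# reference characteristic; approx. 15% unweighting.
subject:
  mass_kg: 75
  height_m: 1.75
  cog_height_m: 0.98
cords:
- characteristic: reference_adult_thick
  cog_level_angle_deg: 45
  elongation_mm: 250
  azimuth_deg: 45
- characteristic: reference_adult_thick
  cog_level_angle_deg: 45
  elongation_mm: 250
  azimuth_deg: 135
- characteristic: reference_adult_thick
  cog_level_angle_deg: 45
  elongation_mm: 250
  azimuth_deg: 225
- characteristic: reference_adult_thick
  cog_level_angle_deg: 45
  elongation_mm: 250
  azimuth_deg: 315
stance:
  left_foot_m: [0.0, 0.15, 0.0]
  right_foot_m: [0.0, -0.15, 0.0]
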