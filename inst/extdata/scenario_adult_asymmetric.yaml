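# Adult verticalization, asymmetric setup for one-sided stimulation:
# 75 kg subject; cords 1 and 2 at 250 mm / 45 deg, cord 3 at 240 mm /
# 6 deg, cord 4 at 310 mm / 48 deg. The low-angle cord acts almost
# horizontally, shifting load to one side.
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
  cog_level_angle_deg: 6
  elongation_mm: 240
  azimuth_deg: 225
- characteristic: reference_adult_thick
  cog_level_angle_deg: 48
  elongation_mm: 310
  azimuth_deg: 315
stance:
  left_foot_m: [0.0, 0.15, 0.0]
  right_foot_m: [0.0, -0.15, 0.0]
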