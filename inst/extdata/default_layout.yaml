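n_spokes: 10
holes_per_spoke: 3
hole_radial_centers_mm:
- 12.5
- 25.0
- 38.0
diameter_first_spoke_mm: 7.0
diameter_last_spoke_mm: 1.5
spoke_angle_step_deg: 36.0
per_slice_base_angle_deg:
  '8': 90.0
  '9': 90.0
  '10': 90.0
  '11': 90.0
lcod_slice_indices_1based:
- 8
- 9
- 10
- 11
slice_contrasts_pct:
  '8': 1.4
  '9': 2.5
  '10': 3.6
  '11': 5.1
inner_disk_radius_mm: 45.0
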