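# Default echowss pipeline configuration: straight 3.2 mm phantom at
# 20 mL/min imaged at 23.44 MHz, 2-cycle pulses, 10,000 fps, 1100 frames.
geometry:
  kind: straight
  diameter_mm: 3.2
  length_mm: 8
  stenosis_severity: 0
  stenosis_length_mm: 4
  stenosis_center_mm: .na
  eccentric: true
  malapposition_offset_mm: 0
  strut_pitch_mm: 1.0
  strut_extent_mm: 4
fluid:
  mu_pa_s: 0.0009
  rho_kg_m3: 998
flow:
  flow_rate_ml_min: 20
acquisition:
  fc_hz: 2.344e+7
  n_cycles: 2
  c_mps: 1480
  frame_rate_hz: 1.0e+4
  n_frames: 1100
  lambda_lat_mm: 0.25
  sigma_lat_mm: 0.05
  sigma_to_mm: 0.1
  dz_mm: 0.05
  dx_mm: 0.05
  lateral_margin_mm: 0.6
  concentration_per_ml: 2.5e+6
  slice_thickness_mm: 0.3
  clutter_db: 40
  snr_db: 20
  to_enabled: true
estimation:
  n_discard: 1
  loess_span: 0.10
  K: 20
  ma_span: 0.03
  zero_threshold_mps: .na
  power_mask_db: 20
  wall_margin_mm: .na
metrics:
  trim_mm: 0.5
seed: 1
out_dir: echowss-out
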