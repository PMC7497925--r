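id: Lung 5
led_mode: phantom
scenarios:
- M0S0
- M1S0
- M1S1
seed: 1
case:
  mean_amplitude_x: 2
  mean_amplitude_y: 10
  mean_amplitude_z: 6
  mean_period: 5
  'n': 2
  phase_shift_z: 0.0
  surrogate_mean_amplitude: 6
  surrogate_phase_shift: 0.0
  amplitude_rel_sd: 0.1
  period_sd: 0.5
  smoothing_window: 5.0
  drift_amplitude: 0.0
  duration: 252
  sample_interval: 0.0125
delivery:
  gantry_period: 12.0
  kv_per_rotation: 4
  treatment_duration: 252
  led_interval: 0.0125
  jaw_width_iso: 25.0
  kv_noise_sd: 0.3
  model_window: 10
  warmup_fixes: 6
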