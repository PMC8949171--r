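# Example run configuration; unset keys fall back to package defaults
# (see ?default_run_config). Units: *_mm keys in millimetres, everything
# else SI.
simulate:
  sample_rate: 50000
  tap_rate: 100
  stride_duration: 1.1
  amplitude: 20
  natural_frequency: 1600
  frequency_sd: 100
  damping_ratio: 0.5
  damping_sd: 0.05
  positions_mm: [15, 25, 35, 45]
  snr: 4
  band: [100, 5000]
  profile:
    kind: walking
    peak_speed: 55
delay:
  template_length_ms: 2
  delta_search_ms: 0.5
  min_speed: 10
  max_speed: 150
kalman:
  constraints: consecutive
  position_sd_mm: 0.5
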