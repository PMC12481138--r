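# pitchcoach default run configuration.
# Values mirror the live training system's documented defaults where it
# states one; the rest are this package's documented choices.
pitch:
  f_min: 50            # Hz, lower edge of the adjustable pitch range
  f_max: 600           # Hz, upper edge
  window_length: 0.04  # s
  hop: 0.01            # s
  voicing_threshold: 0.45
  median_filter_width: 5
targets:
  constant_hz: 200     # default constant-exercise target
  stair_low_hz: 110
  stair_high_hz: 200   # middle level is set midway automatically
  tolerance: 100       # band half-width
  tolerance_unit: cents
exercise:
  dwell_advance_s: 1   # chanting hum-phase dwell before auto-advance
  chant_duration_s: 3
  constant_i_duration_s: 5
  stair_duration_s: 6
volume:
  quiet_medium_dbfs: -40
  medium_loud_dbfs: -20
  onset_threshold_dbfs: -40
validation:
  tones_hz: [110, 155, 200, 300]
  duration_s: 3
  sample_rate_hz: 44100
  max_deviation_hz: 5
stats:
  alpha: 0.05
  sus_benchmark: 70
seed: 1
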