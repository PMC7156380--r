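# Default run configuration. Empty paths mean: generate synthetic records
# (samples, carbonate) or use the bundled tables (crustal_reference,
# hypsometry). Parameter-range overrides mirror the mass-balance prior table
# field-for-field, e.g.
#   ranges:
#     d98mo_red: {min: -2.8, max: -0.8}
paths:
  samples: ""
  carbonate: ""
  crustal_reference: ""
  hypsometry: ""
grid:
  n: 31
  f_min: 0.001
  f_max: 1.0
runs_per_scenario: 1000
seed: 1
filter:
  mode: range
  n_bins: 10
timeseries:
  enabled: false
  t_start: 444.7
  t_end: 440.8
  dt: 0.02
  n_bins: 10
riverine_multiplier: 1
output_dir: paleoredox_run
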