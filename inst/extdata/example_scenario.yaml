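# Example MEA treatment-course scenario: a small two-group experiment.
# Keys mirror the well/design/params sections of the run configuration;
# anything omitted takes the package default.
seed: 7
well:
  n_electrodes: 16
  duration: 60
  base_rate: 2
  burst_rate: 6
  burst_duration: 0.3
  burst_gain: 5
  coupling_kind: paired
  coupling_n_pairs: 4
  coupling_weight: 0.2
design:
  n_days: 3
  rate_multipliers: [1.0, 1.9, 2.5]
  coupling_boost: 3
  n_treated_wells: 3
  n_control_wells: 3
params:
  bin_width: 0.05
  z_min: 0.80
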