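name: lower_salaries
perspective: societal
overrides:
  nurse_hourly: 150.0
  physiotherapist_hourly: 120.0
exclusions: []
imputation: mice
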