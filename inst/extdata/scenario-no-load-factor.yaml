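name: no_load_factor
perspective: societal
overrides:
  load_factor: 1.0
exclusions: []
imputation: mice
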