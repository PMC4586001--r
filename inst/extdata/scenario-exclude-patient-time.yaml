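name: exclude_patient_time
perspective: societal
overrides: {}
exclusions:
  - patient_time
imputation: mice
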