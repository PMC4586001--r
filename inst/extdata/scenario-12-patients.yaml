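name: patients_per_course_12
perspective: societal
overrides:
  patients_per_course: 12
exclusions: []
imputation: mice
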