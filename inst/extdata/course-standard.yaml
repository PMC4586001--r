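# Standard arm: one 8-week course, planned role-hours (no interviews,
# team evaluations or expert patients)
arm: standard
patients_per_course: 10
nurse:
  training_h: 36
  education_h: 8
physiotherapist:
  training_h: 36
  education_h: 4
expert_patient: {}
expert_transport_cost_total: 0
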