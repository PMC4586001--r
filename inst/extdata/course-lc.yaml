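# Learning-and-coping arm: one 8-week course, planned role-hours
arm: LC
patients_per_course: 10
nurse:
  training_h: 36     # 1.5 h x 3/week x 8 weeks
  education_h: 8
  interview_h: 10    # initial + final individual interviews, 1 h each
  team_eval_h: 8     # weekly team evaluation
physiotherapist:
  training_h: 36
  education_h: 4
  interview_h: 10
  team_eval_h: 8
expert_patient:
  training_h: 12
  education_h: 12
  team_eval_h: 8
  transport_time_h: 16
expert_transport_cost_total: 2304   # per course, hospital-paid (fixture constant)
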