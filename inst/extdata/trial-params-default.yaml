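'n':
  LC: 413.0
  standard: 412.0
age_mean:
  LC: 63.0
  standard: 63.0
age_sd:
  LC: 10.0
  standard: 10.0
age_range:
  LC:
  - 33.0
  - 92.0
  standard:
  - 27.0
  - 89.0
male_prop:
  LC: 0.76
  standard: 0.76
ihd_prop:
  LC: 0.79
  standard: 0.78
attend_training_mean:
  LC: 19.609999999999999
  standard: 18.48
attend_training_sd:
  LC: 5.0
  standard: 5.0
attend_training_range:
- 1.0
- 24.0
attend_education_mean:
  LC: 6.46
  standard: 5.97
attend_education_sd:
  LC: 2.5
  standard: 2.5
attend_education_range:
- 0.0
- 9.0
interviews:
  LC: 2.0
  standard: 0.0
utility_times:
- 0.0
- 2.0
- 5.0
utility_mean:
  LC:
  - 0.72
  - 0.771
  - 0.788
  standard:
  - 0.705
  - 0.754
  - 0.782
utility_sd:
  LC:
  - 0.121934408597409
  - 0.121934408597409
  - 0.121934408597409
  standard:
  - 0.121786698781107
  - 0.121786698781107
  - 0.121786698781107
utility_cor: 0.6
cost_table:
- category: gp
  mean_LC: 1361.0
  mean_standard: 1314.0
  sd_LC: 1227.879494575913213
  sd_standard: 1346.351955025133748
- category: specialist
  mean_LC: 252.0
  mean_standard: 234.0
  sd_LC: 673.890831515016203
  sd_standard: 723.615968591075216
- category: physio
  mean_LC: 120.0
  mean_standard: 112.0
  sd_LC: 576.140080622759683
  sd_standard: 527.945339216097295
- category: dentist
  mean_LC: 186.0
  mean_standard: 160.0
  sd_LC: 292.236132605124681
  sd_standard: 209.067166240899724
- category: other_primary
  mean_LC: 28.0
  mean_standard: 31.0
  sd_LC: 192.453141569577923
  sd_standard: 255.752067440323913
- category: medicine_rx
  mean_LC: 2064.0
  mean_standard: 2022.0
  sd_LC: 1934.286168383571976
  sd_standard: 2201.294580468502318
- category: outpatient
  mean_LC: 44050.0
  mean_standard: 41513.0
  sd_LC: 16258.124370335588537
  sd_standard: 20671.66829544243592
- category: admissions
  mean_LC: 17644.0
  mean_standard: 19250.0
  sd_LC: 62121.719924107863335
  sd_standard: 61451.944382295987452
weeks_table:
- category: sick
  mean_LC: 2.13
  mean_standard: 2.33
  sd_LC: 6.299944444199488
  sd_standard: 6.292312770357176
- category: reschooling
  mean_LC: 0.02
  mean_standard: 0.05
  sd_LC: 0.406448028658032
  sd_standard: 1.014889156509222
- category: disability
  mean_LC: 2.12
  mean_standard: 1.6
  sd_LC: 6.299944444199488
  sd_standard: 5.683379276451643
cost_utility_cor: -0.3
nonresponse_rate: 0.43
missing_mechanism: MAR
beta_cost: 1.0
beta_attend: -0.5
post_admission_prob: 0.08
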