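# Unit costs for the cardiac rehabilitation education programme, price year 2013 (DKK)
price_year: 2013
load_factor: 1.5
overhead_rate: 0.21
items:
  nurse_hourly: 197.0            # hospital gross salary
  physiotherapist_hourly: 160.0  # hospital gross salary
  expert_patient_hourly: 108.0   # pensioner net salary, 65 years old
  expert_transport_per_way: 49.0 # paid by the hospital
  patient_transport_per_km: 3.82 # government tariff, private car
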