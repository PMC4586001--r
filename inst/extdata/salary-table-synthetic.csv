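gender,age_min,age_max,gross_hourly,net_hourly
male,18,24,118,104
male,25,29,142,125
male,30,34,156,137
male,35,39,166,146
male,40,44,173,152
male,45,49,176,155
male,50,54,173,152
male,55,59,168,148
male,60,64,164,144
male,65,69,152,133
male,70,74,140,123
male,75,120,130,114
female,18,24,96,80
female,25,29,116,96
female,30,34,127,105
female,35,39,136,113
female,40,44,141,117
female,45,49,144,119
female,50,54,141,117
female,55,59,137,114
female,60,64,134,111
female,65,69,124,103
female,70,74,114,94
female,75,120,106,88
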