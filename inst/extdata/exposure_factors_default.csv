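age_lower,age_upper,body_weight_kg,intake_rate,intake_units
0,1,8,7,m3/day
1,10,25,14,m3/day
10,20,58,21,m3/day
20,60,80,19,m3/day
60,,78,16,m3/day
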