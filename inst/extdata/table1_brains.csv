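brain,sex,age_years,cause_of_death,fresh_brain_weight_g
BC04,male,75,Acute glomerulonephritis,1349
BC05,female,59,Cardiorespiratory insufficiency,1142
BC08,female,72,Renal failure,1216
BC09,female,79,Cardiorespiratory insufficiency,1110
BC10,female,85,Mesenteric infarction,1046
BC11,male,74,Myocardial infarction,1381
BC13,male,39,Drowning,1234
BC14,female,86,Cardiorespiratory insufficiency,1113
BC20,male,65,Cardiorespiratory insufficiency,1392
BC21,male,30,Bronchopneumonia,1409
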