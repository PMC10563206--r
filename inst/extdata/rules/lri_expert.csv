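RuleSet,lri_expert,expert,authored
Diagnosis,LRI
CONDITION,CONDITION,CONDITION,CONDITION,CONDITION,CONDITION,CONDITION,ACTION,ACTION
hospital_days gt,age ge,body_temperature_max in_range,has_pct_lab eq,cough_sputum eq,ir_pulmonary_infiltrate eq,sputum_micro_positive eq,rule_id,probability
2,,"38.0,41.0",,1,1,,20101,0.5
2,65,"38.0,41.0",1,,,,20102,0.5
2,,,,,1,1,20103,0.9
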