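RuleSet,uti_guideline,guideline,authored
Diagnosis,UTI
CONDITION,CONDITION,CONDITION,CONDITION,CONDITION,CONDITION,CONDITION,ACTION,ACTION
body_temperature_max in_range,hospital_days gt,urine_wbc gt,urine_wbc_abnormal eq,urine_bacteria_abnormal eq,urinary_symptoms eq,urine_micro_positive eq,rule_id,probability
"38.0,41.0",2,,1,,1,,60101,0.5
,2,10,,1,,,60102,0.5
,2,,,,,1,60103,0.9
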