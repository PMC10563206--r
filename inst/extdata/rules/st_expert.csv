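RuleSet,st_expert,expert,authored
Diagnosis,ST
CONDITION,CONDITION,CONDITION,ACTION,ACTION
body_temperature_max in_range,skin_infection_note eq,wound_micro_positive eq,rule_id,probability
"38.0,41.0",1,,90101,0.5
,1,1,90102,0.9
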