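RuleSet,pci_guideline,guideline,authored
Diagnosis,PCI
CONDITION,CONDITION,CONDITION,CONDITION,CONDITION,ACTION,ACTION
body_temperature_max in_range,chest_pain eq,ir_pleural_effusion eq,pleural_wbc gt,pleural_micro_positive eq,rule_id,probability
"38.0,41.0",1,1,1000,,10301,0.5
"38.0,41.0",,,1000,1,10302,0.9
,,1,,1,10303,0.9
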