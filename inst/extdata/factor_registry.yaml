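# Factor registry: every infection factor the pipeline may extract, with its
# kind, unit and owning case-tuple group. Rules may only reference ids listed
# here; a case carrying an unregistered id is a validation issue, not an error.
factors:
# DE - demographics
- {id: age, kind: integer, unit: years, group: DE, description: patient age at admission}
- {id: gender, kind: binary, unit: '', group: DE, description: '1 = male, 0 = female'}
# PS - hospitalization status
- {id: admission_datetime, kind: date, unit: '', group: PS, description: admission timestamp}
- {id: hospital_days, kind: integer, unit: days, group: PS, description: calendar hospital day (admission day = 1)}
# VS - vital signs
- {id: body_temperature_max, kind: real, unit: degC, group: VS, description: highest body temperature of the day}
- {id: defecation_frequency, kind: integer, unit: per_day, group: VS, description: number of bowel movements on the day}
# CL - clinical laboratory and microbiology
- {id: pct, kind: real, unit: ng/mL, group: CL, description: procalcitonin, latest result on or before the day}
- {id: has_pct_lab, kind: binary, unit: '', group: CL, description: whether the patient has a PCT lab result}
- {id: crp, kind: real, unit: mg/L, group: CL, description: C-reactive protein, latest result}
- {id: blood_wbc, kind: real, unit: 10^9/L, group: CL, description: blood white blood cell count}
- {id: urine_wbc, kind: real, unit: 10^6/L, group: CL, description: urinary fluid leukocyte number}
- {id: urine_wbc_abnormal, kind: binary, unit: '', group: CL, description: urinary fluid leukocyte abnormal flag}
- {id: urine_bacteria_abnormal, kind: binary, unit: '', group: CL, description: urinary bacteria count abnormal flag}
- {id: pleural_wbc, kind: real, unit: 10^6/L, group: CL, description: pleural effusion fluid leukocyte count}
- {id: pleural_micro_positive, kind: binary, unit: '', group: CL, description: positive culture or smear from pleural effusion}
- {id: urine_micro_positive, kind: binary, unit: '', group: CL, description: positive urine culture}
- {id: sputum_micro_positive, kind: binary, unit: '', group: CL, description: positive sputum culture}
- {id: wound_micro_positive, kind: binary, unit: '', group: CL, description: positive wound secretion culture}
- {id: blood_micro_positive, kind: binary, unit: '', group: CL, description: positive blood culture}
# PN - progress-note keyword flags
- {id: chest_pain, kind: binary, unit: '', group: PN, description: chest pain documented in progress notes}
- {id: purulent_pleural_effusion, kind: binary, unit: '', group: PN, description: purulent or foul-smelling pleural effusion documented}
- {id: urinary_symptoms, kind: binary, unit: '', group: PN, description: frequent urination, urgent urination, dysuria or urine pain documented}
- {id: cough_sputum, kind: binary, unit: '', group: PN, description: productive cough / purulent sputum documented}
- {id: icterus, kind: binary, unit: '', group: PN, description: icterus documented}
- {id: runny_nose, kind: binary, unit: '', group: PN, description: runny nose documented}
- {id: skin_infection_note, kind: binary, unit: '', group: PN, description: purulent discharge or local redness and swelling documented}
# IR - imaging-report keyword flags
- {id: ir_pleural_effusion, kind: binary, unit: '', group: IR, description: pleural effusion described in imaging report}
- {id: ir_pulmonary_infiltrate, kind: binary, unit: '', group: IR, description: pulmonary infiltrate / consolidation described in imaging report}
# OP - operations
- {id: recent_operation, kind: binary, unit: '', group: OP, description: operation performed during the episode on or before the day}
# MO - medical orders
- {id: urinary_catheter, kind: binary, unit: '', group: MO, description: urinary catheter order active on the day}
- {id: ventilator, kind: binary, unit: '', group: MO, description: ventilator order active on the day}
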