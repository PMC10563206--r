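# Keyword lexicon for text-derived binary factors. Matching is substring
# search on case-folded, whitespace-normalized text, sentence by sentence;
# a sentence containing a negation cue does not count as evidence.
# English defaults; lexicons are language-agnostic and fully configurable.
default_negation_cues: ["no ", "denies", "without", "rule out", "free of"]
entries:
- factor_id: chest_pain
  note_type: progress
  keywords: ["chest pain"]
- factor_id: purulent_pleural_effusion
  note_type: progress
  keywords: ["purulent pleural effusion", "foul-smelling pleural effusion"]
- factor_id: urinary_symptoms
  note_type: progress
  keywords: ["frequent urination", "urgent urination", "dysuria", "urine pain"]
- factor_id: cough_sputum
  note_type: progress
  keywords: ["productive cough", "purulent sputum", "cough with sputum"]
- factor_id: icterus
  note_type: progress
  keywords: ["icterus", "jaundice"]
- factor_id: runny_nose
  note_type: progress
  keywords: ["runny nose"]
- factor_id: skin_infection_note
  note_type: progress
  keywords: ["purulent discharge", "local redness and swelling", "wound infection"]
- factor_id: ir_pleural_effusion
  note_type: imaging
  keywords: ["pleural effusion"]
- factor_id: ir_pulmonary_infiltrate
  note_type: imaging
  keywords: ["pulmonary infiltrate", "patchy opacity", "consolidation"]
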