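# El-Serag expert rule: a colonoscopy is screening iff the patient has NO
# claim matching any of 28 disqualifying symptom/condition categories in
# the diagnosis lookback window AND no colonoscopy procedure code in the 4
# years before the index exam.
#
# The original rule enumerates 28 ICD-9 codes; that inventory is not
# reproduced here, so the default ships 28 named categories (a superset of
# the symptom/condition predictor categories) with SYNTHETIC codes.  The
# nine categories that overlap the predictor dictionary reuse its codes so
# the rule engages on generated claims; the rest carry placeholder codes.
# The diagnosis lookback is not stated by the rule's users; it defaults to
# the same 4 years as the colonoscopy clause.
colonoscopy_lookback_days: 1460
colonoscopy_codes:
  - {code_system: billing-procedure, code: SYN-COL01}
  - {code_system: CCP, code: SYN-COL02}
disqualifying:
  - {category: rectal_bleeding,        lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-569.3}, {code_system: ICD-10, code: SYN-K62.5}]}
  - {category: diarrhea,               lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-787.91}, {code_system: ICD-10, code: SYN-R19.7}]}
  - {category: vomiting,               lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-787.0}]}
  - {category: weight_loss,            lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-783.2}]}
  - {category: anemia,                 lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-280.9}, {code_system: ICD-10, code: SYN-D50.9}]}
  - {category: crc,                    lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-153.9}, {code_system: ICD-10, code: SYN-C18.9}]}
  - {category: colorectal_polyps,      lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-211.3}, {code_system: ICD-10, code: SYN-D12.6}]}
  - {category: crohns_disease,         lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-555.9}]}
  - {category: ulcerative_colitis,     lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-556.9}]}
  - {category: large_bowel_disease,    lookback_days: 1460, codes: [{code_system: ICD-10, code: SYN-K63.9H}]}
  - {category: abdominal_pain,         lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-789.0}]}
  - {category: constipation,           lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-564.0}]}
  - {category: change_bowel_habit,     lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-787.99}]}
  - {category: melena,                 lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-578.1}]}
  - {category: occult_blood_positive,  lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-792.1}]}
  - {category: iron_deficiency,        lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-280.1}]}
  - {category: diverticulitis,         lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-562.11}]}
  - {category: diverticulosis,         lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-562.10}]}
  - {category: hemorrhoids,            lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-455.6}]}
  - {category: anal_fissure,           lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-565.0}]}
  - {category: intestinal_obstruction, lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-560.9}]}
  - {category: ileostomy_colostomy,    lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-V44.3}]}
  - {category: personal_hx_crc,        lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-V10.05}]}
  - {category: personal_hx_polyps,     lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-V12.72}]}
  - {category: gi_hemorrhage,          lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-578.9}]}
  - {category: proctitis,              lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-569.49}]}
  - {category: irritable_bowel,        lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-564.1}]}
  - {category: colitis_unspecified,    lookback_days: 1460, codes: [{code_system: ICD-9, code: SYN-558.9}]}
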