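# Claims code dictionary: predictor category -> code set + lookback window.
#
# Codes here are SYNTHETIC placeholders (prefix SYN-): the real provincial
# code inventories (RAMQ / CCP / ICD-9 / ICD-10 / CCI) are not public in a
# reusable form.  Edit this file to run against real claims.  Lookback
# windows use fixed day counts: 1 y = 365, 4 y = 1460, 5 y = 1825.
categories:
  colonoscopy:
    record_type: procedure
    lookback_days: 1460
    codes:
      - {code_system: billing-procedure, code: SYN-COL01}
      - {code_system: CCP, code: SYN-COL02}
  polypectomy:
    record_type: procedure
    lookback_days: 1460
    codes:
      - {code_system: billing-procedure, code: SYN-POL01}
      - {code_system: CCP, code: SYN-POL02}
  sigmoidoscopy:
    record_type: procedure
    lookback_days: 1460
    codes:
      - {code_system: billing-procedure, code: SYN-SIG01}
      - {code_system: CCP, code: SYN-SIG02}
  dcbe:
    record_type: procedure
    lookback_days: 1460
    codes:
      - {code_system: billing-procedure, code: SYN-DCB01}
  rectal_bleeding:
    record_type: diagnosis
    lookback_days: 365
    codes:
      - {code_system: ICD-9, code: SYN-569.3}
      - {code_system: ICD-10, code: SYN-K62.5}
  diarrhea:
    record_type: diagnosis
    lookback_days: 365
    codes:
      - {code_system: ICD-9, code: SYN-787.91}
      - {code_system: ICD-10, code: SYN-R19.7}
  vomiting:
    record_type: diagnosis
    lookback_days: 365
    codes:
      - {code_system: ICD-9, code: SYN-787.0}
  weight_loss:
    record_type: diagnosis
    lookback_days: 365
    codes:
      - {code_system: ICD-9, code: SYN-783.2}
  anemia:
    record_type: diagnosis
    lookback_days: 365
    codes:
      - {code_system: ICD-9, code: SYN-280.9}
      - {code_system: ICD-10, code: SYN-D50.9}
  crc:
    record_type: diagnosis
    lookback_days: 1825
    codes:
      - {code_system: ICD-9, code: SYN-153.9}
      - {code_system: ICD-10, code: SYN-C18.9}
  colorectal_polyps:
    record_type: diagnosis
    lookback_days: 1825
    codes:
      - {code_system: ICD-9, code: SYN-211.3}
      - {code_system: ICD-10, code: SYN-D12.6}
  ibd:
    record_type: diagnosis
    lookback_days: 1825
    codes:
      - {code_system: ICD-9, code: SYN-555.9}
      - {code_system: ICD-9, code: SYN-556.9}
  large_bowel_hospitalization:
    record_type: hospitalization
    lookback_days: 1825
    codes:
      - {code_system: ICD-10, code: SYN-K63.9H}
  large_bowel_surgery:
    record_type: surgery
    lookback_days: 1825
    codes:
      - {code_system: CCI, code: SYN-1NM87}
      - {code_system: CCP, code: SYN-57.49}
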