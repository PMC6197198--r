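patient_id,feature_id,feature_type,timestamp
P1,ICD250.00,diagnosis,2009-11-15T00:00:00Z
P1,SNM_candidiasis,condition,2009-12-20T10:15:00Z
P1,LAB_urine_drug_panel,lab,2009-12-28T07:45:00Z
P2,ICD584.9,diagnosis,2010-01-20T00:00:00Z
P3,SNM_chronic_renal_failure,condition,2010-02-11T16:00:00Z
P3,LAB_inr,lab,2010-02-25T08:00:00Z
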