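patient_id,ingredient,dose_quantity,frequency,route,unit,timestamp
P1,tacrolimus,10,1,oral,mg,2010-01-01T08:00:00Z
P1,tacrolimus,5,1,oral,mg,2010-01-03T08:00:00Z
P1,tacrolimus,5,1,oral,mg,2010-01-05T08:00:00Z
P2,tacrolimus,10,2,oral,mg,2010-02-01T08:00:00Z
P2,tacrolimus,10,2,oral,mg,2010-02-04T08:00:00Z
P3,warfarin,5,1,oral,mg,2010-03-01T09:30:00Z
P3,warfarin,7.5,1,oral,mg,2010-03-10T09:30:00Z
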