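child,parent
SNM_candidiasis,SNM_mycosis
SNM_mycosis,SNM_infectious_disease
SNM_chronic_renal_failure,SNM_renal_failure
SNM_renal_failure,SNM_kidney_disease
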