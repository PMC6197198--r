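{
  "2C9": ["warfarin", "losartan", "phenytoin"],
  "3A4": ["tacrolimus", "sildenafil", "itraconazole"],
  "L_antineoplastic_immunomodulating": ["tacrolimus", "methotrexate"]
}
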