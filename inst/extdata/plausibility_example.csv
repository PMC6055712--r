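product_code,drug_class,qty_min,qty_max,ndd_min,ndd_max,dur_min,dur_max,default_qty,default_ndd,default_duration_days
PA,drug,1,500,0.5,12,1,186,56,2,28
PB,drug,1,500,0.5,12,1,186,56,2,28
PC,drug,1,500,0.5,12,1,186,56,2,28
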