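patient_id,entry,exit,event_date
p1,0,365,
p2,0,365,
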