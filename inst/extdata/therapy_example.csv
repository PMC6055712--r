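patient_id,product_code,start_date,qty,ndd,numdays,dose_duration
p1,PA,0,28,1,,
p1,PA,28,5000,1,,
p1,PA,56,56,2,,
p1,PA,56,14,2,,
p1,PA,80,28,,,
p1,PA,120,28,0,,
p1,PC,200,,,999,
p1,PB,210,56,2,,
p2,PA,10,84,3,,
p2,PA,30,84,3,,
p2,PA,350,84,3,,
p2,PB,100,28,1,30,
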