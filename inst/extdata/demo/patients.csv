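"patient_id","sex","birth_year","death_date"
"A","female",1960,""
"B","male",1975,""
"C","female",1950,"2019-06-01"
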