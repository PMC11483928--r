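"patient_id","code","date","confirmed"
"A","L40.1","2016-03-01",TRUE
"A","L40.1","2016-04-01",TRUE
"A","L40.0","2016-05-01",TRUE
"B","L40.1","2017-01-10",TRUE
"B","L40.1","2017-02-10",TRUE
"C","L40.1","2018-02-01",TRUE
"C","L40.1","2018-03-01",TRUE
"C","I21.0","2017-06-01",TRUE
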