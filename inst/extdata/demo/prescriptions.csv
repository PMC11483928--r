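"patient_id","drug_code","date","days_supply"
"A","etretinate","2016-03-05",30
"A","etretinate","2016-04-04",30
"A","secukinumab","2016-08-20",
"B","cyclosporin","2017-01-15",30
"B","cyclosporin","2017-02-14",30
"C","etretinate","2018-02-05",30
"C","topical_corticosteroid","2018-02-05",30
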