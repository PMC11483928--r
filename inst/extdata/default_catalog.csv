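"drug_code","drug_name","category1","category2","default_coverage_days","priority","is_supplementary","gap_class"
"secukinumab","Secukinumab","Biologics","IL-17 inhibitors",28,1,FALSE,"biologic"
"ixekizumab","Ixekizumab","Biologics","IL-17 inhibitors",28,1,FALSE,"biologic"
"brodalumab","Brodalumab","Biologics","IL-17 inhibitors",28,1,FALSE,"biologic"
"adalimumab","Adalimumab","Biologics","TNF-alpha inhibitors",28,2,FALSE,"biologic"
"infliximab","Infliximab","Biologics","TNF-alpha inhibitors",56,2,FALSE,"biologic"
"certolizumab_pegol","Certolizumab pegol","Biologics","TNF-alpha inhibitors",28,2,FALSE,"biologic"
"guselkumab","Guselkumab","Biologics","IL-23 inhibitors",56,3,FALSE,"biologic"
"risankizumab","Risankizumab","Biologics","IL-23 inhibitors",84,3,FALSE,"biologic"
"ustekinumab","Ustekinumab","Biologics","IL-23 inhibitors",84,3,FALSE,"biologic"
"etretinate","Etretinate","Systemic oral medications","Etretinate",30,4,FALSE,"oral"
"cyclosporin","Cyclosporin","Systemic oral medications","Cyclosporin",30,5,FALSE,"oral"
"systemic_corticosteroid","Systemic corticosteroid","Systemic oral medications","Corticosteroids",30,7,FALSE,"oral"
"apremilast","Apremilast","Systemic oral medications","Apremilast",30,8,FALSE,"oral"
"methotrexate","Methotrexate","Systemic oral medications","Methotrexate",30,9,FALSE,"oral"
"antihistamine","Antihistamine","Systemic oral medications","Other oral medications",30,11,TRUE,"oral"
"immunosuppressant","Immunosuppressant","Systemic oral medications","Other oral medications",30,11,TRUE,"oral"
"apheresis","Apheresis/plasma exchange","Apheresis/plasma exchange","Apheresis/plasma exchange",1,6,FALSE,"other"
"topical_corticosteroid","Topical corticosteroid","Topical therapy","Topical therapy",30,10,TRUE,"other"
"topical_vitamin_d3","Topical vitamin D3","Topical therapy","Topical therapy",30,10,TRUE,"other"
"topical_agent","Topical agent (other)","Topical therapy","Topical therapy",30,10,TRUE,"other"
"arthritis_treatment","Arthritis treatment","Arthritis treatment","Arthritis treatment",30,12,TRUE,"other"
"nsaid","NSAID","Arthritis treatment","Arthritis treatment",30,12,TRUE,"other"
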