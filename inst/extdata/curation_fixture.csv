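"compound_id","smiles","assay_id","value","unit","qualifier","endpoint"
"K01","CO","A1",1,"uM","=","IC50"
"K02","CCO","A1",1,"uM","=","IC50"
"K03","CCCO","A1",1,"uM","=","IC50"
"K04","CCCCO","A1",1,"uM","=","IC50"
"K05","CCCCCO","A1",1,"uM","=","IC50"
"K06","CCCCCCO","A1",1,"uM","=","IC50"
"K07","CCCCCCCO","A1",1,"uM","=","IC50"
"K08","CCCCCCCCO","A1",1,"uM","=","IC50"
"K09","CCCCCCCCCO","A1",1,"uM","=","IC50"
"K10","CCCCCCCCCCO","A1",1,"uM","=","IC50"
"K11","CCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K12","CCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K13","CCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K14","CCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K15","CCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K16","CCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K17","CCCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K18","CCCCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K19","CCCCCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K20","CCCCCCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K21","CCCCCCCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K22","CCCCCCCCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"K23","CCCCCCCCCCCCCCCCCCCCCCCO","A1",1,"uM","=","IC50"
"X01","XX99","A1",1,"uM","=","IC50"
"Q01","CCN","A1",1,"uM","<","IC50"
"Q02","CCCN","A1",1,"uM",">","IC50"
"M01","CCCCN","A1",,"uM","=","IC50"
"N01","CCCCCN","A1",-1,"uM","=","IC50"
"U01","CCCCCCN","A1",1,"kg","=","IC50"
"L01","CCCCCCCN","A1",6.5,"logged","=","IC50"
"R01","CCCCCCCCN","A1",10,"mM","=","IC50"
"R02","CCCCCCCCCN","A1",1,"fM","=","IC50"
"REP1","c1ccccc1N","A1",10,"uM","=","IC50"
"REP1","c1ccccc1N","A1",10,"nM","=","IC50"
"REP2","c1ccccc1CN","A1",1,"uM","=","IC50"
"REP2","c1ccccc1CN","A1",0.398107170553497,"uM","=","IC50"
"REP2","c1ccccc1CN","A1",0.1,"uM","=","IC50"
"D01","Oc1ccccc1","A1",1,"uM","=","IC50"
"D02","C1=CC=CC=C1O","A1",0.1,"uM","=","IC50"
"H01","CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC","A1",1,"uM","=","IC50"
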