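species,CA,CB,CQ,TC0,TCM,D_juvenile,D_adult,adult_cutoff_cm,note
ATF,0.1250,-0.1990,2.497,20.512,26.000,346,306,40,
PC,0.0350,-0.1220,3.079,10.957,25.901,365,329,55,adult cutoff printed as 5 cm in source table; 55 cm adopted to match the juvenile bound (<55 cm)
PH,0.0625,-0.1076,3.084,12.970,18.000,365,365,82,foraging days assumed
SBL,0.4200,-0.3300,2.200,18.000,23.000,365,365,45,foraging days assumed
WEP,0.1190,-0.4600,2.600,10.000,15.000,365,365,40,
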