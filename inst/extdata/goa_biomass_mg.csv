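species,year,partition,biomass_mg,scalar
ATF,1990,GOA,1660800,
ATF,1993,GOA,1773450,
ATF,1996,GOA,1770270,
ATF,1999,GOA,1835310,
ATF,2001,GOA,1957130,
ATF,2003,GOA,2035310,
ATF,2005,GOA,2069910,
ATF,2007,GOA,2054040,
ATF,2009,GOA,1962540,
ATF,2011,GOA,1826620,
ATF,2013,GOA,1701770,
ATF,2015,GOA,1571460,
PC,1990,GOA,583841,
PC,1993,GOA,516782,
PC,1996,GOA,429292,
PC,1999,GOA,320235,
PC,2001,GOA,286165,
PC,2003,GOA,292752,
PC,2005,GOA,247481,
PC,2007,GOA,246629,
PC,2009,GOA,307285,
PC,2011,GOA,345269,
PC,2013,GOA,316926,
PC,2015,GOA,312414,
PH,1996,GOA,799683,0.782
PH,1999,GOA,726201,0.847
PH,2001,GOA,583773,0.798
PH,2003,GOA,528888,0.810
PH,2005,GOA,432273,0.853
PH,2007,GOA,406418,0.838
PH,2009,GOA,351987,0.730
PH,2011,GOA,319782,0.742
PH,2013,GOA,339740,0.742
PH,2015,GOA,301639,0.740
SBL,1990,GOA,251000,
SBL,1993,GOA,261000,
SBL,1996,GOA,200000,
SBL,1999,GOA,183000,
SBL,2001,GOA,182000,
SBL,2003,GOA,202000,
SBL,2005,GOA,197000,
SBL,2007,GOA,183000,
SBL,2009,GOA,164000,
SBL,2011,GOA,181000,
SBL,2013,GOA,157000,
SBL,2015,GOA,140000,
WEP,1990,GOA,1479000,
WEP,1990,SE,26101,
WEP,1993,GOA,1748000,
WEP,1993,SE,12337,
WEP,1996,GOA,1013000,
WEP,1996,SE,75596,
WEP,1999,GOA,737000,
WEP,1999,SE,31836,
WEP,2001,GOA,625000,
WEP,2001,SE,28979,
WEP,2003,GOA,1021000,
WEP,2003,SE,26658,
WEP,2005,GOA,713000,
WEP,2005,SE,36901,
WEP,2007,GOA,580000,
WEP,2007,SE,41075,
WEP,2009,GOA,1170000,
WEP,2009,SE,47885,
WEP,2011,GOA,1330000,
WEP,2011,SE,66969,
WEP,2013,GOA,1277000,
WEP,2013,SE,39879,
WEP,2015,GOA,1771000,
WEP,2015,SE,26173,
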