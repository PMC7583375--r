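species,assessed_min_length_cm,cpue_prefiltered,lw_a,lw_b
ATF,19,FALSE,0.0042,3.20
PC,0,FALSE,0.0070,3.10
PH,82,TRUE,0.0069,3.24
SBL,45,FALSE,0.0094,3.03
WEP,37,FALSE,0.0055,3.08
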