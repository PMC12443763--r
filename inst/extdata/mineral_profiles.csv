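mineral,r_m_percent,biopersistence_years,avg_dsr,avg_dsr_se
crocidolite,0.52,66,1.78,0.008
amosite,0.11,77,1.36,0.009
chrysotile,0.0009,0.3,1.92,0.014
libby_amphiboles,0.03,49,0.65,0.02
anthophyllite,0.056,245,0.62,0.02
erionite,4.67,181,1.94,0.02
balangeroite,0.045,55,0.69,0.03
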