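mineral,exposure_source,length_bin,width_bin,dsr
crocidolite,airborne_pooley,<1,<0.125,0.63
crocidolite,airborne_pooley,1-2,<0.125,1.20
crocidolite,airborne_pooley,2-3,<0.125,2.66
crocidolite,airborne_pooley,3-4,<0.125,3.57
crocidolite,airborne_pooley,4-6,<0.125,2.49
crocidolite,airborne_pooley,6-8,<0.125,1.95
crocidolite,airborne_pooley,8-10,<0.125,1.53
crocidolite,airborne_pooley,>10,<0.125,NA
crocidolite,airborne_pooley,<1,0.125-0.250,0.22
crocidolite,airborne_pooley,1-2,0.125-0.250,0.32
crocidolite,airborne_pooley,2-3,0.125-0.250,0.64
crocidolite,airborne_pooley,3-4,0.125-0.250,0.79
crocidolite,airborne_pooley,4-6,0.125-0.250,1.20
crocidolite,airborne_pooley,6-8,0.125-0.250,1.52
crocidolite,airborne_pooley,8-10,0.125-0.250,1.82
crocidolite,airborne_pooley,>10,0.125-0.250,2.30
crocidolite,airborne_pooley,<1,0.250-0.375,0.00
crocidolite,airborne_pooley,1-2,0.250-0.375,0.24
crocidolite,airborne_pooley,2-3,0.250-0.375,0.49
crocidolite,airborne_pooley,3-4,0.250-0.375,0.98
crocidolite,airborne_pooley,4-6,0.250-0.375,0.99
crocidolite,airborne_pooley,6-8,0.250-0.375,2.15
crocidolite,airborne_pooley,8-10,0.250-0.375,0.95
crocidolite,airborne_pooley,>10,0.250-0.375,1.92
crocidolite,airborne_pooley,<1,>0.375,NA
crocidolite,airborne_pooley,1-2,>0.375,0.00
crocidolite,airborne_pooley,2-3,>0.375,0.06
crocidolite,airborne_pooley,3-4,>0.375,0.08
crocidolite,airborne_pooley,4-6,>0.375,0.26
crocidolite,airborne_pooley,6-8,>0.375,0.10
crocidolite,airborne_pooley,8-10,>0.375,1.15
crocidolite,airborne_pooley,>10,>0.375,1.15
crocidolite,dimensional_db,<1,<0.125,0.67
crocidolite,dimensional_db,1-2,<0.125,3.19
crocidolite,dimensional_db,2-3,<0.125,5.12
crocidolite,dimensional_db,3-4,<0.125,4.08
crocidolite,dimensional_db,4-6,<0.125,2.88
crocidolite,dimensional_db,6-8,<0.125,0.91
crocidolite,dimensional_db,8-10,<0.125,0.88
crocidolite,dimensional_db,>10,<0.125,0.27
crocidolite,dimensional_db,<1,0.125-0.250,0.14
crocidolite,dimensional_db,1-2,0.125-0.250,0.93
crocidolite,dimensional_db,2-3,0.125-0.250,1.53
crocidolite,dimensional_db,3-4,0.125-0.250,1.52
crocidolite,dimensional_db,4-6,0.125-0.250,1.15
crocidolite,dimensional_db,6-8,0.125-0.250,0.55
crocidolite,dimensional_db,8-10,0.125-0.250,0.63
crocidolite,dimensional_db,>10,0.125-0.250,0.23
crocidolite,dimensional_db,<1,0.250-0.375,0.00
crocidolite,dimensional_db,1-2,0.250-0.375,0.43
crocidolite,dimensional_db,2-3,0.250-0.375,0.72
crocidolite,dimensional_db,3-4,0.250-0.375,0.52
crocidolite,dimensional_db,4-6,0.250-0.375,0.90
crocidolite,dimensional_db,6-8,0.250-0.375,0.15
crocidolite,dimensional_db,8-10,0.250-0.375,0.42
crocidolite,dimensional_db,>10,0.250-0.375,0.27
crocidolite,dimensional_db,<1,>0.375,NA
crocidolite,dimensional_db,1-2,>0.375,0.00
crocidolite,dimensional_db,2-3,>0.375,0.12
crocidolite,dimensional_db,3-4,>0.375,0.10
crocidolite,dimensional_db,4-6,>0.375,0.05
crocidolite,dimensional_db,6-8,>0.375,0.02
crocidolite,dimensional_db,8-10,>0.375,0.09
crocidolite,dimensional_db,>10,>0.375,0.07
amosite,airborne_pooley,<1,<0.125,0.33
amosite,airborne_pooley,1-2,<0.125,1.49
amosite,airborne_pooley,2-3,<0.125,2.04
amosite,airborne_pooley,3-4,<0.125,3.87
amosite,airborne_pooley,4-6,<0.125,2.38
amosite,airborne_pooley,6-8,<0.125,2.40
amosite,airborne_pooley,8-10,<0.125,1.26
amosite,airborne_pooley,>10,<0.125,0.26
amosite,airborne_pooley,<1,0.125-0.250,0.23
amosite,airborne_pooley,1-2,0.125-0.250,0.73
amosite,airborne_pooley,2-3,0.125-0.250,1.61
amosite,airborne_pooley,3-4,0.125-0.250,2.06
amosite,airborne_pooley,4-6,0.125-0.250,1.49
amosite,airborne_pooley,6-8,0.125-0.250,1.47
amosite,airborne_pooley,8-10,0.125-0.250,1.46
amosite,airborne_pooley,>10,0.125-0.250,0.70
amosite,airborne_pooley,<1,0.250-0.375,0.42
amosite,airborne_pooley,1-2,0.250-0.375,0.42
amosite,airborne_pooley,2-3,0.250-0.375,0.97
amosite,airborne_pooley,3-4,0.250-0.375,1.14
amosite,airborne_pooley,4-6,0.250-0.375,1.35
amosite,airborne_pooley,6-8,0.250-0.375,6.46
amosite,airborne_pooley,8-10,0.250-0.375,1.34
amosite,airborne_pooley,>10,0.250-0.375,2.18
amosite,airborne_pooley,<1,>0.375,NA
amosite,airborne_pooley,1-2,>0.375,0.13
amosite,airborne_pooley,2-3,>0.375,0.25
amosite,airborne_pooley,3-4,>0.375,0.52
amosite,airborne_pooley,4-6,>0.375,0.64
amosite,airborne_pooley,6-8,>0.375,0.52
amosite,airborne_pooley,8-10,>0.375,0.78
amosite,airborne_pooley,>10,>0.375,1.20
amosite,dimensional_db,<1,<0.125,0.33
amosite,dimensional_db,1-2,<0.125,2.30
amosite,dimensional_db,2-3,<0.125,6.00
amosite,dimensional_db,3-4,<0.125,4.94
amosite,dimensional_db,4-6,<0.125,6.05
amosite,dimensional_db,6-8,<0.125,3.70
amosite,dimensional_db,8-10,<0.125,8.35
amosite,dimensional_db,>10,<0.125,1.08
amosite,dimensional_db,<1,0.125-0.250,0.15
amosite,dimensional_db,1-2,0.125-0.250,1.15
amosite,dimensional_db,2-3,0.125-0.250,3.55
amosite,dimensional_db,3-4,0.125-0.250,3.55
amosite,dimensional_db,4-6,0.125-0.250,1.88
amosite,dimensional_db,6-8,0.125-0.250,1.59
amosite,dimensional_db,8-10,0.125-0.250,2.98
amosite,dimensional_db,>10,0.125-0.250,0.41
amosite,dimensional_db,<1,0.250-0.375,0.36
amosite,dimensional_db,1-2,0.250-0.375,0.53
amosite,dimensional_db,2-3,0.250-0.375,1.67
amosite,dimensional_db,3-4,0.250-0.375,2.22
amosite,dimensional_db,4-6,0.250-0.375,4.87
amosite,dimensional_db,6-8,0.250-0.375,0.99
amosite,dimensional_db,8-10,0.250-0.375,1.66
amosite,dimensional_db,>10,0.250-0.375,0.69
amosite,dimensional_db,<1,>0.375,NA
amosite,dimensional_db,1-2,>0.375,0.22
amosite,dimensional_db,2-3,>0.375,0.41
amosite,dimensional_db,3-4,>0.375,0.69
amosite,dimensional_db,4-6,>0.375,0.35
amosite,dimensional_db,6-8,>0.375,0.19
amosite,dimensional_db,8-10,>0.375,0.51
amosite,dimensional_db,>10,>0.375,0.41
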