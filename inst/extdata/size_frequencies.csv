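mineral,medium,length_bin,width_bin,percent
crocidolite,lung,<1,<0.125,11.91
crocidolite,lung,1-2,<0.125,26.07
crocidolite,lung,2-3,<0.125,14.04
crocidolite,lung,3-4,<0.125,8.84
crocidolite,lung,4-6,<0.125,6.93
crocidolite,lung,6-8,<0.125,1.61
crocidolite,lung,8-10,<0.125,0.76
crocidolite,lung,>10,<0.125,0.57
crocidolite,lung,<1,0.125-0.250,1.09
crocidolite,lung,1-2,0.125-0.250,4.50
crocidolite,lung,2-3,0.125-0.250,4.74
crocidolite,lung,3-4,0.125-0.250,3.66
crocidolite,lung,4-6,0.125-0.250,4.49
crocidolite,lung,6-8,0.125-0.250,2.25
crocidolite,lung,8-10,0.125-0.250,1.21
crocidolite,lung,>10,0.125-0.250,1.12
crocidolite,lung,<1,0.250-0.375,0.00
crocidolite,lung,1-2,0.250-0.375,0.43
crocidolite,lung,2-3,0.250-0.375,0.64
crocidolite,lung,3-4,0.250-0.375,0.65
crocidolite,lung,4-6,0.250-0.375,0.96
crocidolite,lung,6-8,0.250-0.375,0.71
crocidolite,lung,8-10,0.250-0.375,0.64
crocidolite,lung,>10,0.250-0.375,0.94
crocidolite,lung,<1,>0.375,0.00
crocidolite,lung,1-2,>0.375,0.00
crocidolite,lung,2-3,>0.375,0.06
crocidolite,lung,3-4,>0.375,0.07
crocidolite,lung,4-6,>0.375,0.13
crocidolite,lung,6-8,>0.375,0.07
crocidolite,lung,8-10,>0.375,0.19
crocidolite,lung,>10,>0.375,0.38
crocidolite,airborne_pooley,<1,<0.125,18.91
crocidolite,airborne_pooley,1-2,<0.125,21.70
crocidolite,airborne_pooley,2-3,<0.125,5.28
crocidolite,airborne_pooley,3-4,<0.125,2.48
crocidolite,airborne_pooley,4-6,<0.125,2.78
crocidolite,airborne_pooley,6-8,<0.125,0.83
crocidolite,airborne_pooley,8-10,<0.125,0.50
crocidolite,airborne_pooley,>10,<0.125,0.00
crocidolite,airborne_pooley,<1,0.125-0.250,4.99
crocidolite,airborne_pooley,1-2,0.125-0.250,14.14
crocidolite,airborne_pooley,2-3,0.125-0.250,7.43
crocidolite,airborne_pooley,3-4,0.125-0.250,4.63
crocidolite,airborne_pooley,4-6,0.125-0.250,3.75
crocidolite,airborne_pooley,6-8,0.125-0.250,1.49
crocidolite,airborne_pooley,8-10,0.125-0.250,0.67
crocidolite,airborne_pooley,>10,0.125-0.250,0.49
crocidolite,airborne_pooley,<1,0.250-0.375,0.17
crocidolite,airborne_pooley,1-2,0.250-0.375,1.81
crocidolite,airborne_pooley,2-3,0.250-0.375,1.32
crocidolite,airborne_pooley,3-4,0.250-0.375,0.66
crocidolite,airborne_pooley,4-6,0.250-0.375,0.98
crocidolite,airborne_pooley,6-8,0.250-0.375,0.33
crocidolite,airborne_pooley,8-10,0.250-0.375,0.67
crocidolite,airborne_pooley,>10,0.250-0.375,0.49
crocidolite,airborne_pooley,<1,>0.375,0.00
crocidolite,airborne_pooley,1-2,>0.375,0.15
crocidolite,airborne_pooley,2-3,>0.375,0.99
crocidolite,airborne_pooley,3-4,>0.375,0.83
crocidolite,airborne_pooley,4-6,>0.375,0.49
crocidolite,airborne_pooley,6-8,>0.375,0.66
crocidolite,airborne_pooley,8-10,>0.375,0.17
crocidolite,airborne_pooley,>10,>0.375,0.33
crocidolite,dimensional_db,<1,<0.125,17.80
crocidolite,dimensional_db,1-2,<0.125,8.17
crocidolite,dimensional_db,2-3,<0.125,2.74
crocidolite,dimensional_db,3-4,<0.125,2.17
crocidolite,dimensional_db,4-6,<0.125,2.41
crocidolite,dimensional_db,6-8,<0.125,1.78
crocidolite,dimensional_db,8-10,<0.125,0.87
crocidolite,dimensional_db,>10,<0.125,2.15
crocidolite,dimensional_db,<1,0.125-0.250,7.63
crocidolite,dimensional_db,1-2,0.125-0.250,4.82
crocidolite,dimensional_db,2-3,0.125-0.250,3.10
crocidolite,dimensional_db,3-4,0.125-0.250,2.40
crocidolite,dimensional_db,4-6,0.125-0.250,3.90
crocidolite,dimensional_db,6-8,0.125-0.250,4.08
crocidolite,dimensional_db,8-10,0.125-0.250,1.91
crocidolite,dimensional_db,>10,0.125-0.250,4.87
crocidolite,dimensional_db,<1,0.250-0.375,0.20
crocidolite,dimensional_db,1-2,0.250-0.375,1.01
crocidolite,dimensional_db,2-3,0.250-0.375,0.90
crocidolite,dimensional_db,3-4,0.250-0.375,1.25
crocidolite,dimensional_db,4-6,0.250-0.375,1.07
crocidolite,dimensional_db,6-8,0.250-0.375,4.80
crocidolite,dimensional_db,8-10,0.250-0.375,1.53
crocidolite,dimensional_db,>10,0.250-0.375,3.46
crocidolite,dimensional_db,<1,>0.375,0.00
crocidolite,dimensional_db,1-2,>0.375,0.11
crocidolite,dimensional_db,2-3,>0.375,0.49
crocidolite,dimensional_db,3-4,>0.375,0.69
crocidolite,dimensional_db,4-6,>0.375,2.64
crocidolite,dimensional_db,6-8,>0.375,3.57
crocidolite,dimensional_db,8-10,>0.375,2.05
crocidolite,dimensional_db,>10,>0.375,5.45
amosite,lung,<1,<0.125,2.24
amosite,lung,1-2,<0.125,8.30
amosite,lung,2-3,<0.125,5.53
amosite,lung,3-4,<0.125,3.71
amosite,lung,4-6,<0.125,2.64
amosite,lung,6-8,<0.125,0.81
amosite,lung,8-10,<0.125,0.41
amosite,lung,>10,<0.125,0.21
amosite,lung,<1,0.125-0.250,1.09
amosite,lung,1-2,0.125-0.250,8.84
amosite,lung,2-3,0.125-0.250,9.22
amosite,lung,3-4,0.125-0.250,7.92
amosite,lung,4-6,0.125-0.250,6.15
amosite,lung,6-8,0.125-0.250,2.97
amosite,lung,8-10,0.125-0.250,2.10
amosite,lung,>10,0.125-0.250,1.01
amosite,lung,<1,0.250-0.375,0.27
amosite,lung,1-2,0.250-0.375,2.43
amosite,lung,2-3,0.250-0.375,4.18
amosite,lung,3-4,0.250-0.375,3.12
amosite,lung,4-6,0.250-0.375,4.73
amosite,lung,6-8,0.250-0.375,3.24
amosite,lung,8-10,0.250-0.375,1.29
amosite,lung,>10,0.250-0.375,2.47
amosite,lung,<1,>0.375,0.00
amosite,lung,1-2,>0.375,0.34
amosite,lung,2-3,>0.375,1.49
amosite,lung,3-4,>0.375,1.75
amosite,lung,4-6,>0.375,3.17
amosite,lung,6-8,>0.375,1.49
amosite,lung,8-10,>0.375,1.63
amosite,lung,>10,>0.375,5.42
amosite,airborne_pooley,<1,<0.125,6.86
amosite,airborne_pooley,1-2,<0.125,5.58
amosite,airborne_pooley,2-3,<0.125,2.71
amosite,airborne_pooley,3-4,<0.125,0.96
amosite,airborne_pooley,4-6,<0.125,1.11
amosite,airborne_pooley,6-8,<0.125,0.34
amosite,airborne_pooley,8-10,<0.125,0.32
amosite,airborne_pooley,>10,<0.125,0.81
amosite,airborne_pooley,<1,0.125-0.250,4.80
amosite,airborne_pooley,1-2,0.125-0.250,12.13
amosite,airborne_pooley,2-3,0.125-0.250,5.73
amosite,airborne_pooley,3-4,0.125-0.250,3.85
amosite,airborne_pooley,4-6,0.125-0.250,4.14
amosite,airborne_pooley,6-8,0.125-0.250,2.01
amosite,airborne_pooley,8-10,0.125-0.250,1.44
amosite,airborne_pooley,>10,0.125-0.250,1.45
amosite,airborne_pooley,<1,0.250-0.375,0.64
amosite,airborne_pooley,1-2,0.250-0.375,5.76
amosite,airborne_pooley,2-3,0.250-0.375,4.31
amosite,airborne_pooley,3-4,0.250-0.375,2.73
amosite,airborne_pooley,4-6,0.250-0.375,3.51
amosite,airborne_pooley,6-8,0.250-0.375,0.50
amosite,airborne_pooley,8-10,0.250-0.375,0.96
amosite,airborne_pooley,>10,0.250-0.375,1.13
amosite,airborne_pooley,<1,>0.375,0.00
amosite,airborne_pooley,1-2,>0.375,2.70
amosite,airborne_pooley,2-3,>0.375,6.05
amosite,airborne_pooley,3-4,>0.375,3.37
amosite,airborne_pooley,4-6,>0.375,4.93
amosite,airborne_pooley,6-8,>0.375,2.85
amosite,airborne_pooley,8-10,>0.375,2.08
amosite,airborne_pooley,>10,>0.375,4.52
amosite,dimensional_db,<1,<0.125,6.74
amosite,dimensional_db,1-2,<0.125,3.61
amosite,dimensional_db,2-3,<0.125,0.92
amosite,dimensional_db,3-4,<0.125,0.75
amosite,dimensional_db,4-6,<0.125,0.44
amosite,dimensional_db,6-8,<0.125,0.22
amosite,dimensional_db,8-10,<0.125,0.05
amosite,dimensional_db,>10,<0.125,0.19
amosite,dimensional_db,<1,0.125-0.250,7.37
amosite,dimensional_db,1-2,0.125-0.250,7.71
amosite,dimensional_db,2-3,0.125-0.250,2.59
amosite,dimensional_db,3-4,0.125-0.250,2.23
amosite,dimensional_db,4-6,0.125-0.250,3.27
amosite,dimensional_db,6-8,0.125-0.250,1.87
amosite,dimensional_db,8-10,0.125-0.250,0.70
amosite,dimensional_db,>10,0.125-0.250,2.45
amosite,dimensional_db,<1,0.250-0.375,0.75
amosite,dimensional_db,1-2,0.250-0.375,4.61
amosite,dimensional_db,2-3,0.250-0.375,2.50
amosite,dimensional_db,3-4,0.250-0.375,1.41
amosite,dimensional_db,4-6,0.250-0.375,0.97
amosite,dimensional_db,6-8,0.250-0.375,3.27
amosite,dimensional_db,8-10,0.250-0.375,0.78
amosite,dimensional_db,>10,0.250-0.375,3.56
amosite,dimensional_db,<1,>0.375,0.00
amosite,dimensional_db,1-2,>0.375,1.53
amosite,dimensional_db,2-3,>0.375,3.66
amosite,dimensional_db,3-4,>0.375,2.52
amosite,dimensional_db,4-6,>0.375,9.12
amosite,dimensional_db,6-8,>0.375,7.83
amosite,dimensional_db,8-10,>0.375,3.20
amosite,dimensional_db,>10,>0.375,13.19
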