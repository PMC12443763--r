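mineral,length_bin,width_bin,gm_width_um,avg_aspect_ratio,pulmonary_deposition_rate
crocidolite,<1,<0.125,0.07,9.33,0.11
crocidolite,1-2,<0.125,0.07,18.03,0.09
crocidolite,2-3,<0.125,0.08,33.86,0.07
crocidolite,3-4,<0.125,0.08,46.14,0.06
crocidolite,4-6,<0.125,0.08,61.33,0.05
crocidolite,6-8,<0.125,0.09,79.81,0.03
crocidolite,8-10,<0.125,0.09,101.61,0.02
crocidolite,>10,<0.125,0.09,305.53,0.01
crocidolite,<1,0.125-0.250,0.15,4.84,0.08
crocidolite,1-2,0.125-0.250,0.15,8.77,0.07
crocidolite,2-3,0.125-0.250,0.15,16.31,0.06
crocidolite,3-4,0.125-0.250,0.16,21.41,0.06
crocidolite,4-6,0.125-0.250,0.17,29.84,0.06
crocidolite,6-8,0.125-0.250,0.17,39.30,0.06
crocidolite,8-10,0.125-0.250,0.18,50.59,0.06
crocidolite,>10,0.125-0.250,0.17,185.11,0.06
crocidolite,<1,0.250-0.375,0.26,3.36,NA
crocidolite,1-2,0.250-0.375,0.29,4.98,0.07
crocidolite,2-3,0.250-0.375,0.31,8.13,0.07
crocidolite,3-4,0.250-0.375,0.31,11.41,0.07
crocidolite,4-6,0.250-0.375,0.30,17.05,0.07
crocidolite,6-8,0.250-0.375,0.30,23.15,0.07
crocidolite,8-10,0.250-0.375,0.30,29.87,0.07
crocidolite,>10,0.250-0.375,0.30,80.04,0.07
crocidolite,<1,>0.375,NA,NA,NA
crocidolite,1-2,>0.375,0.41,3.87,0.09
crocidolite,2-3,>0.375,0.45,5.72,0.10
crocidolite,3-4,>0.375,0.49,7.25,0.11
crocidolite,4-6,>0.375,0.55,10.00,0.10
crocidolite,6-8,>0.375,0.58,12.44,0.10
crocidolite,8-10,>0.375,0.59,15.94,0.10
crocidolite,>10,>0.375,0.69,34.25,0.07
amosite,<1,<0.125,0.09,7.03,0.09
amosite,1-2,<0.125,0.09,16.84,0.07
amosite,2-3,<0.125,0.09,28.66,0.05
amosite,3-4,<0.125,0.09,38.44,0.05
amosite,4-6,<0.125,0.10,54.89,0.05
amosite,6-8,<0.125,0.11,63.90,0.05
amosite,8-10,<0.125,0.11,83.78,0.05
amosite,>10,<0.125,0.09,576.30,0.08
amosite,<1,0.125-0.250,0.16,4.47,0.08
amosite,1-2,0.125-0.250,0.18,8.11,0.07
amosite,2-3,0.125-0.250,0.18,13.64,0.06
amosite,3-4,0.125-0.250,0.17,20.80,0.06
amosite,4-6,0.125-0.250,0.19,26.77,0.06
amosite,6-8,0.125-0.250,0.21,32.92,0.06
amosite,8-10,0.125-0.250,0.20,45.53,0.06
amosite,>10,0.125-0.250,0.19,88.43,0.06
amosite,<1,0.250-0.375,0.26,3.42,0.08
amosite,1-2,0.250-0.375,0.30,4.91,0.07
amosite,2-3,0.250-0.375,0.30,8.22,0.07
amosite,3-4,0.250-0.375,0.32,10.86,0.07
amosite,4-6,0.250-0.375,0.30,17.16,0.07
amosite,6-8,0.250-0.375,0.29,23.01,0.07
amosite,8-10,0.250-0.375,0.30,29.97,0.07
amosite,>10,0.250-0.375,0.31,54.38,0.07
amosite,<1,>0.375,NA,NA,NA
amosite,1-2,>0.375,0.47,3.57,0.09
amosite,2-3,>0.375,0.54,4.75,0.10
amosite,3-4,>0.375,0.64,5.62,0.12
amosite,4-6,>0.375,0.62,8.86,0.11
amosite,6-8,>0.375,0.63,11.07,0.11
amosite,8-10,>0.375,0.67,14.06,0.09
amosite,>10,>0.375,0.68,35.30,0.06
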