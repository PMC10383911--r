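country,B11,B12,B13,B14,B15,B16,B21,B22,B31,B32,B33,B55,mmec_total
AT,136,32,139,103,29,69,48,67,18,85,122,124,3595
BE,59,2,71,4,3,39,93,49,0,23,0,62,2127
BG,179,5,129,19,12,148,11,0,110,90,4,3,2855
CY,15,1,29,0,2,0,6,0,0,0,0,0,207
CZ,72,4,28,32,20,47,30,45,4,194,12,55,6691
DE,156,40,157,176,133,114,177,152,17,220,6,212,24055
DK,132,2,93,105,27,55,21,24,0,184,0,175,3226
EE,20,0,16,7,8,1,5,0,0,26,0,14,612
EL,62,81,88,0,25,62,6,7,22,9,0,4,1386
ES,68,58,85,105,80,22,59,58,34,50,0,178,19582
FR,121,97,116,130,118,82,139,143,75,186,142,193,40989
HR,38,0,22,4,7,53,6,2,16,9,34,16,434
HU,74,34,103,66,30,53,17,8,49,135,49,8,7354
IT,136,54,175,17,130,54,50,98,17,21,378,166,13387
LT,82,6,65,72,50,1,28,4,0,147,0,31,2313
LU,3,0,7,2,0,1,0,0,0,1,0,6,149
LV,66,3,72,44,33,9,12,1,0,110,0,42,1763
NL,150,0,53,23,2,134,200,115,0,3,0,54,1805
PL,66,12,40,105,61,98,89,93,1,173,7,67,20542
PT,28,7,24,40,50,22,19,0,1,0,0,68,877
RO,71,28,39,13,25,159,22,16,189,51,88,32,3649
SE,89,0,67,47,85,11,34,55,0,95,0,167,2742
SI,29,6,26,2,2,30,6,0,1,5,0,27,364
SK,89,13,95,27,16,51,18,25,42,164,55,18,3091
UK,155,0,134,8,84,78,126,105,0,182,0,179,5665
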