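vaccine,vaccinations_age_0_5,cases_all_ages,frequency_per_100k
6VAX-F,4092,68,1662
BCG,241,5,2075
COVID19,7267,54,743
DTAP,55155,57,103
DTAPHEPBIP,11606,41,353
DTAPIPV,10939,15,137
DTAPIPVHIB,10861,55,506
DTP,21679,11,51
DTPIPV,504,10,1984
FLU3,9145,7,77
FLU4,5270,14,266
FLUX,2181,18,825
HBHEPB,5236,8,153
HEP,20648,58,281
HEPA,18061,30,166
HIBV,52928,126,238
IPV,36648,44,120
MEN,1239,16,1291
MENB,2790,91,3262
MMR,59053,64,108
MMRV,11873,11,93
PNC,26198,107,408
PNC13,23510,160,681
PPV,4573,16,350
RV1,7858,79,1005
RV5,16921,104,615
RVX,1398,6,429
TYP,233,6,2575
UNK,2840,24,845
VARCEL,43062,31,72
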