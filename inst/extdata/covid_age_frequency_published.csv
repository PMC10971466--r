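age,cases,vaccinations,frequency_label
1,3,851,352
2,2,826,242
3,2,865,231
4,1,1071,93
5,11,2751,399
6,6,1921,312
7,19,2117,897
8,10,2194,455
9,16,2417,661
10,13,2687,483
11,11,3950,278
12,22,6136,358
13,16,4862,329
14,7,5306,131
15,11,6410,171
16,11,8329,132
17,14,10274,136
18,3,7237,41
19,3,7497,40
20,4,8321,48
21,2,8716,22
22,3,9445,31
23,1,10291,9
24,2,10985,18
25,1,11912,8
26,0,12456,<8
27,1,13197,7
28,2,13813,14
29,1,14700,7
30,0,16084,<6
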