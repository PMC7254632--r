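# Synthetic LMS growth-reference table: height-for-age, male, emulating the WHO release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in cm; L, S dimensionless
age_months,L,M,S
0,1,49.8842,0.03795
1,1,54.7244,0.03557
2,1,58.4249,0.03424
3,1,61.4292,0.03328
4,1,63.886,0.03257
5,1,65.9026,0.03204
6,1,67.6236,0.03165
7,1,69.159,0.03141
8,1,70.5994,0.03116
9,1,71.9721,0.03109
10,1,73.2812,0.03102
11,1,74.5411,0.03104
12,1,75.7488,0.03107
13,1,76.9142,0.03116
14,1,78.0458,0.03124
15,1,79.1458,0.03133
16,1,80.2169,0.03144
17,1,81.2563,0.03154
18,1,82.2587,0.03165
19,1,83.2407,0.03172
20,1,84.2153,0.0318
21,1,85.1713,0.03187
22,1,86.0975,0.03194
23,1,86.9829,0.03202
24,1,87.8161,0.03209
25,1,88.5809,0.03216
26,1,89.2829,0.03223
27,1,89.9439,0.0323
28,1,90.5859,0.03236
29,1,91.2306,0.03243
30,1,91.9,0.0325
31,1,92.5957,0.03277
32,1,93.3007,0.03303
33,1,94.0085,0.0333
34,1,94.7125,0.03357
35,1,95.4063,0.03383
36,1,96.0835,0.0341
37,1,96.7456,0.03445
38,1,97.3983,0.0348
39,1,98.0407,0.03515
40,1,98.6723,0.0355
41,1,99.2923,0.03585
42,1,99.9,0.0362
43,1,100.4908,0.03652
44,1,101.0642,0.03683
45,1,101.626,0.03715
46,1,102.1821,0.03747
47,1,102.7382,0.03778
48,1,103.3,0.0381
49,1,103.869,0.03838
50,1,104.4407,0.03867
51,1,105.0125,0.03895
52,1,105.5815,0.03923
53,1,106.1449,0.03952
54,1,106.7,0.0398
55,1,107.2449,0.04003
56,1,107.7815,0.04027
57,1,108.3125,0.0405
58,1,108.8407,0.04073
59,1,109.369,0.04097
60,1,109.9,0.0412
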