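# Synthetic LMS growth-reference table: height-for-age, female, emulating the WHO release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in cm; L, S dimensionless
age_months,L,M,S
0,1,49.1477,0.0379
1,1,53.6872,0.0364
2,1,57.0673,0.03568
3,1,59.8029,0.0352
4,1,62.0899,0.03486
5,1,64.0301,0.03463
6,1,65.7311,0.03448
7,1,67.2823,0.03441
8,1,68.7498,0.03434
9,1,70.1461,0.03433
10,1,71.4818,0.03432
11,1,72.7735,0.03432
12,1,74.015,0.03432
13,1,75.2135,0.03438
14,1,76.3782,0.03443
15,1,77.5099,0.03449
16,1,78.6106,0.03458
17,1,79.6784,0.03466
18,1,80.7079,0.03475
19,1,81.7154,0.0348
20,1,82.7141,0.03486
21,1,83.6936,0.03491
22,1,84.6437,0.03496
23,1,85.5544,0.03502
24,1,86.4153,0.03507
25,1,87.211,0.03516
26,1,87.9464,0.03525
27,1,88.6424,0.03533
28,1,89.3195,0.03542
29,1,89.9985,0.03551
30,1,90.7,0.0356
31,1,91.4272,0.03575
32,1,92.1642,0.0359
33,1,92.903,0.03605
34,1,93.6358,0.0362
35,1,94.3546,0.03635
36,1,95.0515,0.0365
37,1,95.7226,0.03672
38,1,96.3734,0.03693
39,1,97.0102,0.03715
40,1,97.6394,0.03737
41,1,98.2672,0.03758
42,1,98.9,0.0378
43,1,99.5396,0.03802
44,1,100.1814,0.03823
45,1,100.8218,0.03845
46,1,101.4574,0.03867
47,1,102.0846,0.03888
48,1,102.7,0.0391
49,1,103.3042,0.0393
50,1,103.9,0.0395
51,1,104.4875,0.0397
52,1,105.0667,0.0399
53,1,105.6375,0.0401
54,1,106.2,0.0403
55,1,106.7507,0.04045
56,1,107.2889,0.0406
57,1,107.8187,0.04075
58,1,108.3444,0.0409
59,1,108.8701,0.04105
60,1,109.4,0.0412
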