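# Synthetic LMS growth-reference table: weight-for-age, male, emulating the WHO release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in kg; L, S dimensionless
age_months,L,M,S
0,0.3487,3.3464,0.14602
1,0.2297,4.4709,0.13395
2,0.197,5.5675,0.12385
3,0.1738,6.3762,0.11727
4,0.1553,7.0023,0.11316
5,0.1395,7.5105,0.1108
6,0.1257,7.934,0.10958
7,0.1139,8.2931,0.1093
8,0.1021,8.6151,0.10902
9,0.0926,8.9024,0.10914
10,0.0831,9.1649,0.10925
11,0.07375,9.4136,0.10942
12,0.0644,9.6479,0.10958
13,0.05663,9.8712,0.10981
14,0.04887,10.0865,0.11005
15,0.0411,10.3002,0.11028
16,0.0337,10.5152,0.11056
17,0.0263,10.7286,0.11083
18,0.0189,10.9385,0.11111
19,0.0122,11.1448,0.11145
20,0.0055,11.3489,0.11179
21,-0.0012,11.5513,0.11214
22,-0.0079,11.7522,0.11248
23,-0.0146,11.9522,0.11282
24,-0.0213,12.1515,0.11316
25,-0.0267,12.3516,0.11352
26,-0.0321,12.5526,0.11388
27,-0.0375,12.7526,0.11424
28,-0.0429,12.9497,0.11461
29,-0.0483,13.142,0.11497
30,-0.0537,13.3278,0.11533
31,-0.05785,13.5062,0.11565
32,-0.062,13.6784,0.11598
33,-0.06615,13.846,0.1163
34,-0.0703,14.0101,0.11662
35,-0.07445,14.1723,0.11695
36,-0.0786,14.3337,0.11727
37,-0.08197,14.4916,0.11763
38,-0.08533,14.6444,0.11798
39,-0.0887,14.7952,0.11834
40,-0.09207,14.947,0.1187
41,-0.09543,15.103,0.11905
42,-0.0988,15.2663,0.11941
43,-0.10255,15.4397,0.11981
44,-0.1063,15.6212,0.12021
45,-0.11005,15.8069,0.12062
46,-0.1138,15.9928,0.12102
47,-0.11755,16.1748,0.12142
48,-0.1213,16.3489,0.12182
49,-0.12355,16.5131,0.12222
50,-0.1258,16.6701,0.12261
51,-0.12805,16.8233,0.12301
52,-0.1303,16.9759,0.12341
53,-0.13255,17.1313,0.1238
54,-0.1348,17.2928,0.1242
55,-0.13743,17.461,0.12453
56,-0.14007,17.6333,0.12486
57,-0.1427,17.8085,0.1252
58,-0.14533,17.985,0.12553
59,-0.14797,18.1615,0.12586
60,-0.1506,18.3366,0.12619
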