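# Synthetic LMS growth-reference table: weight-for-age, female, emulating the WHO release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in kg; L, S dimensionless
age_months,L,M,S
0,0.3809,3.2322,0.14171
1,0.1714,4.1873,0.13724
2,0.0962,5.1282,0.13
3,0.0402,5.8458,0.12619
4,-0.005,6.4237,0.12402
5,-0.043,6.8985,0.12274
6,-0.0756,7.297,0.12204
7,-0.1017,7.6387,0.12191
8,-0.1278,7.9474,0.12178
9,-0.1472,8.2251,0.12207
10,-0.1666,8.48,0.12236
11,-0.18155,8.7201,0.12276
12,-0.1965,8.9481,0.12315
13,-0.20717,9.1701,0.12356
14,-0.21783,9.3867,0.12397
15,-0.2285,9.6008,0.12438
16,-0.2364,9.8129,0.12473
17,-0.2443,10.0227,0.12507
18,-0.2522,10.2315,0.12542
19,-0.25788,10.4408,0.12569
20,-0.26357,10.6505,0.12596
21,-0.26925,10.8597,0.12622
22,-0.27493,11.0678,0.12649
23,-0.28062,11.2739,0.12676
24,-0.2863,11.4775,0.12703
25,-0.29048,11.677,0.12723
26,-0.29467,11.8728,0.12742
27,-0.29885,12.0667,0.12762
28,-0.30303,12.2606,0.12782
29,-0.30722,12.4563,0.12801
30,-0.3114,12.6557,0.12821
31,-0.31397,12.8609,0.12834
32,-0.31653,13.0709,0.12847
33,-0.3191,13.2827,0.1286
34,-0.32167,13.4935,0.12874
35,-0.32423,13.7002,0.12887
36,-0.3268,13.9,0.129
37,-0.32867,14.092,0.12917
38,-0.33053,14.2785,0.12933
39,-0.3324,14.4609,0.1295
40,-0.33427,14.6409,0.12967
41,-0.33613,14.8201,0.12983
42,-0.338,15,0.13
43,-0.33913,15.1805,0.13017
44,-0.34027,15.3603,0.13033
45,-0.3414,15.5392,0.1305
46,-0.34253,15.7172,0.13067
47,-0.34367,15.894,0.13083
48,-0.3448,16.0697,0.131
49,-0.34535,16.2427,0.13133
50,-0.3459,16.4128,0.13167
51,-0.34645,16.5817,0.132
52,-0.347,16.7514,0.13233
53,-0.34755,16.9236,0.13267
54,-0.3481,17.1,0.133
55,-0.3489,17.2814,0.13336
56,-0.3497,17.4665,0.13372
57,-0.3505,17.6541,0.13409
58,-0.3513,17.8429,0.13445
59,-0.3521,18.0317,0.13481
60,-0.3529,18.2193,0.13517
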