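# Synthetic LMS growth-reference table: height-for-age, female, emulating the CDC release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in cm; L, S dimensionless
age_months,L,M,S
60,1,108.4,0.0432
61,1,108.9503,0.04328
62,1,109.5012,0.04337
63,1,110.0523,0.04345
64,1,110.6037,0.04353
65,1,111.1551,0.04362
66,1,111.7063,0.0437
67,1,112.2571,0.04378
68,1,112.8074,0.04387
69,1,113.357,0.04395
70,1,113.9058,0.04403
71,1,114.4535,0.04412
72,1,115,0.0442
73,1,115.5464,0.04428
74,1,116.0938,0.04437
75,1,116.6414,0.04445
76,1,117.1889,0.04453
77,1,117.7357,0.04462
78,1,118.2812,0.0447
79,1,118.8251,0.04478
80,1,119.3667,0.04487
81,1,119.9055,0.04495
82,1,120.441,0.04503
83,1,120.9727,0.04512
84,1,121.5,0.0452
85,1,122.0236,0.04528
86,1,122.5444,0.04537
87,1,123.0625,0.04545
88,1,123.5778,0.04553
89,1,124.0903,0.04562
90,1,124.6,0.0457
91,1,125.1069,0.04578
92,1,125.6111,0.04587
93,1,126.1125,0.04595
94,1,126.6111,0.04603
95,1,127.1069,0.04612
96,1,127.6,0.0462
97,1,128.0896,0.04629
98,1,128.5755,0.04638
99,1,129.0578,0.04648
100,1,129.537,0.04657
101,1,130.0135,0.04666
102,1,130.4875,0.04675
103,1,130.9594,0.04684
104,1,131.4296,0.04693
105,1,131.8984,0.04702
106,1,132.3662,0.04712
107,1,132.8333,0.04721
108,1,133.3,0.0473
109,1,133.7637,0.04739
110,1,134.2225,0.04748
111,1,134.6773,0.04758
112,1,135.1296,0.04767
113,1,135.5805,0.04776
114,1,136.0312,0.04785
115,1,136.483,0.04794
116,1,136.937,0.04803
117,1,137.3945,0.04812
118,1,137.8567,0.04822
119,1,138.3248,0.04831
120,1,138.8,0.0484
121,1,139.2815,0.04846
122,1,139.7676,0.04852
123,1,140.2578,0.04858
124,1,140.7519,0.04863
125,1,141.2494,0.04869
126,1,141.75,0.04875
127,1,142.2534,0.04881
128,1,142.7593,0.04887
129,1,143.2672,0.04892
130,1,143.7769,0.04898
131,1,144.2879,0.04904
132,1,144.8,0.0491
133,1,145.3167,0.04901
134,1,145.8407,0.04892
135,1,146.3703,0.04882
136,1,146.9037,0.04873
137,1,147.4392,0.04864
138,1,147.975,0.04855
139,1,148.5094,0.04846
140,1,149.0407,0.04837
141,1,149.5672,0.04827
142,1,150.087,0.04818
143,1,150.5986,0.04809
144,1,151.1,0.048
145,1,151.5972,0.04773
146,1,152.0958,0.04745
147,1,152.5937,0.04718
148,1,153.0889,0.0469
149,1,153.5792,0.04662
150,1,154.0625,0.04635
151,1,154.5368,0.04607
152,1,155,0.0458
153,1,155.45,0.04552
154,1,155.8847,0.04525
155,1,156.3021,0.04497
156,1,156.7,0.0447
157,1,157.0812,0.04441
158,1,157.4498,0.04412
159,1,157.8055,0.04382
160,1,158.1481,0.04353
161,1,158.4776,0.04324
162,1,158.7937,0.04295
163,1,159.0963,0.04266
164,1,159.3852,0.04237
165,1,159.6602,0.04208
166,1,159.9211,0.04178
167,1,160.1677,0.04149
168,1,160.4,0.0412
169,1,160.6146,0.04103
170,1,160.8095,0.04087
171,1,160.9867,0.0407
172,1,161.1481,0.04053
173,1,161.2957,0.04037
174,1,161.4313,0.0402
175,1,161.5567,0.04003
176,1,161.6741,0.03987
177,1,161.7852,0.0397
178,1,161.8919,0.03953
179,1,161.9962,0.03937
180,1,162.1,0.0392
181,1,162.1998,0.03912
182,1,162.2912,0.03903
183,1,162.375,0.03895
184,1,162.4519,0.03887
185,1,162.5225,0.03878
186,1,162.5875,0.0387
187,1,162.6477,0.03862
188,1,162.7037,0.03853
189,1,162.7562,0.03845
190,1,162.806,0.03837
191,1,162.8537,0.03828
192,1,162.9,0.0382
193,1,162.9431,0.03817
194,1,162.9813,0.03813
195,1,163.0148,0.0381
196,1,163.0444,0.03807
197,1,163.0706,0.03803
198,1,163.0937,0.038
199,1,163.1145,0.03797
200,1,163.1333,0.03793
201,1,163.1508,0.0379
202,1,163.1674,0.03787
203,1,163.1836,0.03783
204,1,163.2,0.0378
205,1,163.2153,0.03779
206,1,163.2282,0.03778
207,1,163.2391,0.03778
208,1,163.2481,0.03777
209,1,163.2558,0.03776
210,1,163.2625,0.03775
211,1,163.2685,0.03774
212,1,163.2741,0.03773
213,1,163.2797,0.03772
214,1,163.2856,0.03772
215,1,163.2923,0.03771
216,1,163.3,0.0377
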