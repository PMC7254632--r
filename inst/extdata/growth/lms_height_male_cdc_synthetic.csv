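# Synthetic LMS growth-reference table: height-for-age, male, emulating the CDC release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in cm; L, S dimensionless
age_months,L,M,S
60,1,109.2,0.0422
61,1,109.7423,0.04228
62,1,110.2856,0.04237
63,1,110.8297,0.04245
64,1,111.3741,0.04253
65,1,111.9185,0.04262
66,1,112.4625,0.0427
67,1,113.0058,0.04278
68,1,113.5481,0.04287
69,1,114.0891,0.04295
70,1,114.6282,0.04303
71,1,115.1653,0.04312
72,1,115.7,0.0432
73,1,116.2326,0.04329
74,1,116.7639,0.04338
75,1,117.2938,0.04348
76,1,117.8222,0.04357
77,1,118.3493,0.04366
78,1,118.875,0.04375
79,1,119.3993,0.04384
80,1,119.9222,0.04393
81,1,120.4437,0.04403
82,1,120.9639,0.04412
83,1,121.4826,0.04421
84,1,122,0.0443
85,1,122.5169,0.04438
86,1,123.034,0.04447
87,1,123.5508,0.04455
88,1,124.0667,0.04463
89,1,124.5812,0.04472
90,1,125.0937,0.0448
91,1,125.6039,0.04488
92,1,126.1111,0.04497
93,1,126.6148,0.04505
94,1,127.1146,0.04513
95,1,127.6098,0.04522
96,1,128.1,0.0453
97,1,128.5858,0.04539
98,1,129.0681,0.04548
99,1,129.5469,0.04557
100,1,130.0222,0.04567
101,1,130.4941,0.04576
102,1,130.9625,0.04585
103,1,131.4274,0.04594
104,1,131.8889,0.04603
105,1,132.3469,0.04612
106,1,132.8014,0.04622
107,1,133.2524,0.04631
108,1,133.7,0.0464
109,1,134.1431,0.04649
110,1,134.5813,0.04658
111,1,135.0148,0.04667
112,1,135.4444,0.04677
113,1,135.8706,0.04686
114,1,136.2937,0.04695
115,1,136.7145,0.04704
116,1,137.1333,0.04713
117,1,137.5508,0.04723
118,1,137.9674,0.04732
119,1,138.3836,0.04741
120,1,138.8,0.0475
121,1,139.2137,0.04762
122,1,139.6225,0.04773
123,1,140.0273,0.04785
124,1,140.4296,0.04797
125,1,140.8305,0.04808
126,1,141.2312,0.0482
127,1,141.633,0.04832
128,1,142.037,0.04843
129,1,142.4445,0.04855
130,1,142.8567,0.04867
131,1,143.2748,0.04878
132,1,143.7,0.0489
133,1,144.1277,0.04905
134,1,144.5537,0.0492
135,1,144.9797,0.04935
136,1,145.4074,0.0495
137,1,145.8386,0.04965
138,1,146.275,0.0498
139,1,146.7183,0.04995
140,1,147.1704,0.0501
141,1,147.6328,0.05025
142,1,148.1074,0.0504
143,1,148.5959,0.05055
144,1,149.1,0.0507
145,1,149.6215,0.0508
146,1,150.1597,0.0509
147,1,150.7125,0.051
148,1,151.2778,0.0511
149,1,151.8535,0.0512
150,1,152.4375,0.0513
151,1,153.0278,0.0514
152,1,153.6222,0.0515
153,1,154.2188,0.0516
154,1,154.8153,0.0517
155,1,155.4097,0.0518
156,1,156,0.0519
157,1,156.594,0.05169
158,1,157.1988,0.05148
159,1,157.8117,0.05128
160,1,158.4296,0.05107
161,1,159.0496,0.05086
162,1,159.6687,0.05065
163,1,160.2841,0.05044
164,1,160.8926,0.05023
165,1,161.4914,0.05002
166,1,162.0775,0.04982
167,1,162.6481,0.04961
168,1,163.2,0.0494
169,1,163.7378,0.04897
170,1,164.2674,0.04855
171,1,164.7883,0.04812
172,1,165.3,0.0477
173,1,165.802,0.04727
174,1,166.2937,0.04685
175,1,166.7747,0.04642
176,1,167.2444,0.046
177,1,167.7023,0.04557
178,1,168.1479,0.04515
179,1,168.5806,0.04472
180,1,169,0.0443
181,1,169.4066,0.04403
182,1,169.8014,0.04375
183,1,170.1844,0.04348
184,1,170.5556,0.0432
185,1,170.9149,0.04292
186,1,171.2625,0.04265
187,1,171.5983,0.04238
188,1,171.9222,0.0421
189,1,172.2344,0.04182
190,1,172.5347,0.04155
191,1,172.8233,0.04128
192,1,173.1,0.041
193,1,173.3627,0.04087
194,1,173.61,0.04073
195,1,173.843,0.0406
196,1,174.063,0.04047
197,1,174.2712,0.04033
198,1,174.4688,0.0402
199,1,174.657,0.04007
200,1,174.837,0.03993
201,1,175.0102,0.0398
202,1,175.1775,0.03967
203,1,175.3404,0.03953
204,1,175.5,0.0394
205,1,175.6517,0.03934
206,1,175.7912,0.03928
207,1,175.9203,0.03922
208,1,176.0407,0.03917
209,1,176.1542,0.03911
210,1,176.2625,0.03905
211,1,176.3673,0.03899
212,1,176.4704,0.03893
213,1,176.5734,0.03888
214,1,176.6782,0.03882
215,1,176.7865,0.03876
216,1,176.9,0.0387
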