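# Synthetic LMS growth-reference table: weight-for-age, female, emulating the CDC release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in kg; L, S dimensionless
age_months,L,M,S
60,-1.8,17.9,0.132
61,-1.81667,18.0907,0.133
62,-1.83333,18.2799,0.134
63,-1.85,18.468,0.135
64,-1.86667,18.6556,0.136
65,-1.88333,18.8431,0.137
66,-1.9,19.0312,0.138
67,-1.91667,19.2204,0.139
68,-1.93333,19.4111,0.14
69,-1.95,19.6039,0.141
70,-1.96667,19.7993,0.142
71,-1.98333,19.9978,0.143
72,-2,20.2,0.144
73,-2.01667,20.4049,0.14517
74,-2.03333,20.6113,0.14633
75,-2.05,20.8195,0.1475
76,-2.06667,21.0296,0.14867
77,-2.08333,21.2418,0.14983
78,-2.1,21.4562,0.151
79,-2.11667,21.6731,0.15217
80,-2.13333,21.8926,0.15333
81,-2.15,22.1148,0.1545
82,-2.16667,22.34,0.15567
83,-2.18333,22.5684,0.15683
84,-2.2,22.8,0.158
85,-2.20833,23.035,0.15925
86,-2.21667,23.2734,0.1605
87,-2.225,23.5148,0.16175
88,-2.23333,23.7593,0.163
89,-2.24167,24.0065,0.16425
90,-2.25,24.2562,0.1655
91,-2.25833,24.5085,0.16675
92,-2.26667,24.763,0.168
93,-2.275,25.0195,0.16925
94,-2.28333,25.278,0.1705
95,-2.29167,25.5382,0.17175
96,-2.3,25.8,0.173
97,-2.3,26.0629,0.174
98,-2.3,26.3269,0.175
99,-2.3,26.5922,0.176
100,-2.3,26.8593,0.177
101,-2.3,27.1284,0.178
102,-2.3,27.4,0.179
103,-2.3,27.6744,0.18
104,-2.3,27.9519,0.181
105,-2.3,28.2328,0.182
106,-2.3,28.5176,0.183
107,-2.3,28.8065,0.184
108,-2.3,29.1,0.185
109,-2.29167,29.3976,0.18575
110,-2.28333,29.6986,0.1865
111,-2.275,30.0031,0.18725
112,-2.26667,30.3111,0.188
113,-2.25833,30.6226,0.18875
114,-2.25,30.9375,0.1895
115,-2.24167,31.2559,0.19025
116,-2.23333,31.5778,0.191
117,-2.225,31.9031,0.19175
118,-2.21667,32.2319,0.1925
119,-2.20833,32.5642,0.19325
120,-2.2,32.9,0.194
121,-2.19167,33.2402,0.19433
122,-2.18333,33.5854,0.19467
123,-2.175,33.9352,0.195
124,-2.16667,34.2889,0.19533
125,-2.15833,34.6461,0.19567
126,-2.15,35.0063,0.196
127,-2.14167,35.3688,0.19633
128,-2.13333,35.7333,0.19667
129,-2.125,36.0992,0.197
130,-2.11667,36.466,0.19733
131,-2.10833,36.8331,0.19767
132,-2.1,37.2,0.198
133,-2.09167,37.5693,0.19783
134,-2.08333,37.9431,0.19767
135,-2.075,38.3203,0.1975
136,-2.06667,38.7,0.19733
137,-2.05833,39.0811,0.19717
138,-2.05,39.4625,0.197
139,-2.04167,39.8432,0.19683
140,-2.03333,40.2222,0.19667
141,-2.025,40.5984,0.1965
142,-2.01667,40.9708,0.19633
143,-2.00833,41.3384,0.19617
144,-2,41.7,0.196
145,-1.99167,42.0576,0.19533
146,-1.98333,42.4134,0.19467
147,-1.975,42.7672,0.194
148,-1.96667,43.1185,0.19333
149,-1.95833,43.4671,0.19267
150,-1.95,43.8125,0.192
151,-1.94167,44.1545,0.19133
152,-1.93333,44.4926,0.19067
153,-1.925,44.8266,0.19
154,-1.91667,45.156,0.18933
155,-1.90833,45.4806,0.18867
156,-1.9,45.8,0.188
157,-1.89167,46.1152,0.18708
158,-1.88333,46.4273,0.18617
159,-1.875,46.7359,0.18525
160,-1.86667,47.0407,0.18433
161,-1.85833,47.3414,0.18342
162,-1.85,47.6375,0.1825
163,-1.84167,47.9288,0.18158
164,-1.83333,48.2148,0.18067
165,-1.825,48.4953,0.17975
166,-1.81667,48.7699,0.17883
167,-1.80833,49.0383,0.17792
168,-1.8,49.3,0.177
169,-1.79167,49.5556,0.17608
170,-1.78333,49.8056,0.17517
171,-1.775,50.05,0.17425
172,-1.76667,50.2889,0.17333
173,-1.75833,50.5222,0.17242
174,-1.75,50.75,0.1715
175,-1.74167,50.9722,0.17058
176,-1.73333,51.1889,0.16967
177,-1.725,51.4,0.16875
178,-1.71667,51.6056,0.16783
179,-1.70833,51.8056,0.16692
180,-1.7,52,0.166
181,-1.69583,52.1886,0.16533
182,-1.69167,52.3711,0.16467
183,-1.6875,52.5477,0.164
184,-1.68333,52.7185,0.16333
185,-1.67917,52.8838,0.16267
186,-1.675,53.0437,0.162
187,-1.67083,53.1985,0.16133
188,-1.66667,53.3481,0.16067
189,-1.6625,53.493,0.16
190,-1.65833,53.6331,0.15933
191,-1.65417,53.7687,0.15867
192,-1.65,53.9,0.158
193,-1.64583,54.0245,0.15758
194,-1.64167,54.1405,0.15717
195,-1.6375,54.2492,0.15675
196,-1.63333,54.3519,0.15633
197,-1.62917,54.4496,0.15592
198,-1.625,54.5438,0.1555
199,-1.62083,54.6354,0.15508
200,-1.61667,54.7259,0.15467
201,-1.6125,54.8164,0.15425
202,-1.60833,54.9081,0.15383
203,-1.60417,55.0022,0.15342
204,-1.6,55.1,0.153
205,-1.6,55.2,0.15275
206,-1.6,55.3,0.1525
207,-1.6,55.4,0.15225
208,-1.6,55.5,0.152
209,-1.6,55.6,0.15175
210,-1.6,55.7,0.1515
211,-1.6,55.8,0.15125
212,-1.6,55.9,0.151
213,-1.6,56,0.15075
214,-1.6,56.1,0.1505
215,-1.6,56.2,0.15025
216,-1.6,56.3,0.15
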