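# Synthetic LMS growth-reference table: weight-for-age, male, emulating the CDC release
# Monthly L (skew) / M (median) / S (coefficient of variation) grid produced by
# monotone-spline interpolation of published anchor medians; NOT a verbatim copy
# of the WHO child growth standards or the CDC 2000 charts. Medians accurate to
# about 1%; see data-raw/make_growth_tables.R for the anchors.
# units: age_months in months; M in kg; L, S dimensionless
age_months,L,M,S
60,-1.7,18.4,0.125
61,-1.71667,18.591,0.12567
62,-1.73333,18.781,0.12633
63,-1.75,18.9703,0.127
64,-1.76667,19.1593,0.12767
65,-1.78333,19.3482,0.12833
66,-1.8,19.5375,0.129
67,-1.81667,19.7275,0.12967
68,-1.83333,19.9185,0.13033
69,-1.85,20.1109,0.131
70,-1.86667,20.3051,0.13167
71,-1.88333,20.5013,0.13233
72,-1.9,20.7,0.133
73,-1.91667,20.9007,0.13383
74,-1.93333,21.1028,0.13467
75,-1.95,21.3062,0.1355
76,-1.96667,21.5111,0.13633
77,-1.98333,21.7174,0.13717
78,-2,21.925,0.138
79,-2.01667,22.134,0.13883
80,-2.03333,22.3444,0.13967
81,-2.05,22.5562,0.1405
82,-2.06667,22.7694,0.14133
83,-2.08333,22.984,0.14217
84,-2.1,23.2,0.143
85,-2.10833,23.417,0.14383
86,-2.11667,23.635,0.14467
87,-2.125,23.8539,0.1455
88,-2.13333,24.0741,0.14633
89,-2.14167,24.2956,0.14717
90,-2.15,24.5188,0.148
91,-2.15833,24.7436,0.14883
92,-2.16667,24.9704,0.14967
93,-2.175,25.1992,0.1505
94,-2.18333,25.4303,0.15133
95,-2.19167,25.6639,0.15217
96,-2.2,25.9,0.153
97,-2.20417,26.1389,0.15375
98,-2.20833,26.3803,0.1545
99,-2.2125,26.6242,0.15525
100,-2.21667,26.8704,0.156
101,-2.22083,27.1186,0.15675
102,-2.225,27.3687,0.1575
103,-2.22917,27.6206,0.15825
104,-2.23333,27.8741,0.159
105,-2.2375,28.1289,0.15975
106,-2.24167,28.385,0.1605
107,-2.24583,28.642,0.16125
108,-2.25,28.9,0.162
109,-2.24583,29.1578,0.16267
110,-2.24167,29.4148,0.16333
111,-2.2375,29.6719,0.164
112,-2.23333,29.9296,0.16467
113,-2.22917,30.1888,0.16533
114,-2.225,30.45,0.166
115,-2.22083,30.714,0.16667
116,-2.21667,30.9815,0.16733
117,-2.2125,31.2531,0.168
118,-2.20833,31.5296,0.16867
119,-2.20417,31.8117,0.16933
120,-2.2,32.1,0.17
121,-2.19167,32.3938,0.1705
122,-2.18333,32.6917,0.171
123,-2.175,32.9938,0.1715
124,-2.16667,33.3,0.172
125,-2.15833,33.6104,0.1725
126,-2.15,33.925,0.173
127,-2.14167,34.2438,0.1735
128,-2.13333,34.5667,0.174
129,-2.125,34.8937,0.1745
130,-2.11667,35.225,0.175
131,-2.10833,35.5604,0.1755
132,-2.1,35.9,0.176
133,-2.09167,36.2434,0.17625
134,-2.08333,36.5905,0.1765
135,-2.075,36.9414,0.17675
136,-2.06667,37.2963,0.177
137,-2.05833,37.6554,0.17725
138,-2.05,38.0187,0.1775
139,-2.04167,38.3867,0.17775
140,-2.03333,38.7593,0.178
141,-2.025,39.1367,0.17825
142,-2.01667,39.5192,0.1785
143,-2.00833,39.9069,0.17875
144,-2,40.3,0.179
145,-1.99167,40.6995,0.17883
146,-1.98333,41.106,0.17867
147,-1.975,41.5187,0.1785
148,-1.96667,41.937,0.17833
149,-1.95833,42.3602,0.17817
150,-1.95,42.7875,0.178
151,-1.94167,43.2183,0.17783
152,-1.93333,43.6519,0.17767
153,-1.925,44.0875,0.1775
154,-1.91667,44.5245,0.17733
155,-1.90833,44.9623,0.17717
156,-1.9,45.4,0.177
157,-1.89167,45.8385,0.1765
158,-1.88333,46.2792,0.176
159,-1.875,46.7219,0.1755
160,-1.86667,47.1667,0.175
161,-1.85833,47.6135,0.1745
162,-1.85,48.0625,0.174
163,-1.84167,48.5135,0.1735
164,-1.83333,48.9667,0.173
165,-1.825,49.4219,0.1725
166,-1.81667,49.8792,0.172
167,-1.80833,50.3385,0.1715
168,-1.8,50.8,0.171
169,-1.79167,51.2661,0.17033
170,-1.78333,51.7384,0.16967
171,-1.775,52.2156,0.169
172,-1.76667,52.6963,0.16833
173,-1.75833,53.1791,0.16767
174,-1.75,53.6625,0.167
175,-1.74167,54.1453,0.16633
176,-1.73333,54.6259,0.16567
177,-1.725,55.1031,0.165
178,-1.71667,55.5755,0.16433
179,-1.70833,56.0416,0.16367
180,-1.7,56.5,0.163
181,-1.69167,56.9547,0.16233
182,-1.68333,57.4095,0.16167
183,-1.675,57.8633,0.161
184,-1.66667,58.3148,0.16033
185,-1.65833,58.7629,0.15967
186,-1.65,59.2062,0.159
187,-1.64167,59.6437,0.15833
188,-1.63333,60.0741,0.15767
189,-1.625,60.4961,0.157
190,-1.61667,60.9086,0.15633
191,-1.60833,61.3103,0.15567
192,-1.6,61.7,0.155
193,-1.59167,62.0779,0.15442
194,-1.58333,62.4454,0.15383
195,-1.575,62.8031,0.15325
196,-1.56667,63.1519,0.15267
197,-1.55833,63.4922,0.15208
198,-1.55,63.825,0.1515
199,-1.54167,64.1508,0.15092
200,-1.53333,64.4704,0.15033
201,-1.525,64.7844,0.14975
202,-1.51667,65.0935,0.14917
203,-1.50833,65.3985,0.14858
204,-1.5,65.7,0.148
205,-1.49583,65.9947,0.14758
206,-1.49167,66.2796,0.14717
207,-1.4875,66.5563,0.14675
208,-1.48333,66.8259,0.14633
209,-1.47917,67.09,0.14592
210,-1.475,67.35,0.1455
211,-1.47083,67.6072,0.14508
212,-1.46667,67.863,0.14467
213,-1.4625,68.1188,0.14425
214,-1.45833,68.3759,0.14383
215,-1.45417,68.6359,0.14342
216,-1.45,68.9,0.143
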