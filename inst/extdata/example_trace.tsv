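# protocol: GOR
# emission_nm: 685
# actinic_umol: 0
time_us	fluorescence
0	100
2	119.23577118547229
4	136.62146790544534
6	152.33502820539132
8	166.53727625314286
10	179.37356833206508
12	190.97528052448709
14	201.46115331144341
16	210.93850685035048
18	219.50433936866631
20	227.24631991530509
22	234.24368563035634
24	240.56805271642858
26	246.28414941169771
28	251.45047846644573
30	256.11991590336379
32	260.34025218977467
34	264.15468136052982
36	267.60224309762577
38	270.71822229110887
40	273.53451017066936
42	276.07993070401159
44	278.380535602603
46	280.45987095410692
48	282.33921821041395
50	284.03781199771913
52	285.57303697787592
54	286.96060577585013
56	288.21471979431476
58	289.34821456128088
60	290.37269109836063
62	291.29863465417964
64	292.13552201814662
66	292.89191851290718
68	293.57556565817424
70	294.19346040315151
72	294.75192673847334
74	295.25668042058993
76	295.7128874710354
78	296.1252170493031
80	296.497889240468
82	296.83471824665065
84	297.13915142437554
86	297.41430456736055
88	297.66299379584842
90	297.88776437885883
92	298.09091678434925
94	298.27453022390068
96	298.44048393290313
98	298.59047640403685
100	298.7260427708992
102	298.84857051969448
104	298.95931368979132
106	299.05940570848645
108	299.149870991336
110	299.23163542678003
112	299.30553585236737
114	299.37232861956932
116	299.43269733483748
118	299.48725985613737
120	299.53657461656212
122	299.58114633974884
124	299.62143120559278
126	299.65784151912862
128	299.69074993036475
130	299.7204932482577
132	299.74737588786422
134	299.77167298594912
136	299.79363321693785
138	299.81348133803419
140	299.83142048955119
142	299.84763427399889
144	299.86228863520824
146	299.87553355672213
148	299.88750459683791
150	299.89832427601112
152	299.90810333081998
154	299.91694184732523
156	299.92493028542492
158	299.9321504046876
160	299.93867610113983
162	299.94457416357324
164	299.94990495710954
166	299.95472304102236
168	299.95907772713679
170	299.96301358452263
172	299.96657089564815
174	299.96978606865935
176	299.97269201000881
178	299.97531846124377
180	299.97769230340396
182	299.9798378321409
184	299.98177700637859
186	299.98352967305669
188	299.98511377025886
190	299.98654551080438
192	299.98783954818236
194	299.98900912652573
196	299.99006621616212
198	299.99102163612667
200	299.9918851648921
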