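# material: hydroxyapatite
# density_g_cm3: 3.18
energy_keV	mu_over_rho
10	34.737672
11	26.144959
12	20.180598
13	15.911725
14	12.776192
15	10.421472
16	8.6188483
17	7.215511
18	6.1067217
19	5.2190552
20	4.5
21	3.9113259
22	3.4247506
23	3.0190457
24	2.6780669
25	2.3893884
26	2.1433405
27	1.932322
28	1.7503023
29	1.5924547
30	1.4548858
31	1.3344311
32	1.2285008
33	1.1349617
34	1.0520458
35	0.97827941
36	0.91242775
37	0.85345073
38	0.80046813
39	0.75273169
40	0.70960251
41	0.67053295
42	0.63505167
43	0.60275158
44	0.57327984
45	0.54632958
46	0.52163309
47	0.49895609
48	0.47809296
49	0.45886276
50	0.44110581
51	0.42468084
52	0.40946255
53	0.39533957
54	0.38221267
55	0.36999322
56	0.35860195
57	0.34796774
58	0.33802674
59	0.32872144
60	0.32
61	0.3118156
62	0.30412585
63	0.29689236
64	0.29008025
65	0.28365782
66	0.27759622
67	0.27186912
68	0.26645247
69	0.26132432
70	0.25646452
71	0.25185463
72	0.24747772
73	0.24331821
74	0.23936178
75	0.23559524
76	0.23200642
77	0.22858408
78	0.22531784
79	0.22219809
80	0.21921593
81	0.21636312
82	0.213632
83	0.21101546
84	0.20850689
85	0.20610014
86	0.20378949
87	0.20156959
88	0.19943547
89	0.19738247
90	0.19540625
91	0.19350274
92	0.19166815
93	0.18989892
94	0.1881917
95	0.18654337
96	0.18495099
97	0.1834118
98	0.18192321
99	0.18048278
100	0.17908821
101	0.17773735
102	0.17642815
103	0.17515871
104	0.1739272
105	0.17273191
106	0.17157125
107	0.17044366
108	0.16934773
109	0.16828207
110	0.16724541
111	0.1662365
112	0.16525421
113	0.16429742
114	0.16336509
115	0.16245623
116	0.16156992
117	0.16070524
118	0.15986136
119	0.15903746
120	0.15823279
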