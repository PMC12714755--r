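# material: walnut_shell
# density_g_cm3: 1.2
energy_keV	mu_over_rho
10	6.1608237
11	4.6811993
12	3.6539672
13	2.9185649
14	2.3782369
15	1.9723068
16	1.6614082
17	1.4192399
18	1.2277744
19	1.0743738
20	0.95
21	0.84807272
22	0.76372401
23	0.69330002
24	0.63402197
25	0.58375105
26	0.54082287
27	0.50392909
28	0.47203162
29	0.44429967
30	0.42006303
31	0.39877697
32	0.37999568
33	0.36335193
34	0.34854134
35	0.33531023
36	0.32344599
37	0.31276955
38	0.30312934
39	0.29439652
40	0.28646108
41	0.27922868
42	0.27261816
43	0.2665594
44	0.26099159
45	0.25586189
46	0.25112416
47	0.24673802
48	0.24266803
49	0.23888301
50	0.23535542
51	0.23206089
52	0.22897782
53	0.22608699
54	0.22337128
55	0.22081538
56	0.21840561
57	0.21612969
58	0.21397657
59	0.21193633
60	0.21
61	0.20815948
62	0.20640743
63	0.2047372
64	0.20314276
65	0.20161861
66	0.20015975
67	0.19876161
68	0.19742
69	0.19613113
70	0.19489148
71	0.19369785
72	0.19254728
73	0.19143707
74	0.19036471
75	0.1893279
76	0.18832452
77	0.1873526
78	0.18641031
79	0.18549599
80	0.18460805
81	0.18374506
82	0.18290567
83	0.18208861
84	0.18129274
85	0.18051696
86	0.17976025
87	0.17902168
88	0.17830035
89	0.17759544
90	0.17690617
91	0.17623183
92	0.17557172
93	0.17492521
94	0.17429171
95	0.17367064
96	0.17306148
97	0.17246374
98	0.17187693
99	0.17130062
100	0.17073439
101	0.17017784
102	0.16963061
103	0.16909233
104	0.16856268
105	0.16804134
106	0.16752801
107	0.16702241
108	0.16652426
109	0.16603332
110	0.16554934
111	0.16507209
112	0.16460135
113	0.16413692
114	0.16367859
115	0.16322617
116	0.16277949
117	0.16233838
118	0.16190266
119	0.16147218
120	0.1610468
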