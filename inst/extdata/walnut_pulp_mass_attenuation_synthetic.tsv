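# material: walnut_pulp
# density_g_cm3: 0.95
energy_keV	mu_over_rho
10	2.713201
11	2.0912273
12	1.6592849
13	1.3499295
14	1.1225193
15	0.95156689
16	0.82053655
17	0.71838042
18	0.63752599
19	0.57266471
20	0.52
21	0.47676783
22	0.44092334
23	0.4109317
24	0.38562564
25	0.36410668
26	0.34567566
27	0.32978297
28	0.31599251
29	0.30395525
30	0.29338964
31	0.2840668
32	0.27579944
33	0.26843326
34	0.26184035
35	0.25591413
36	0.25056523
37	0.2457184
38	0.24130994
39	0.23728568
40	0.23359938
41	0.23021137
42	0.22708751
43	0.22419833
44	0.22151824
45	0.219025
46	0.21669921
47	0.21452386
48	0.21248404
49	0.21056661
50	0.20875997
51	0.20705386
52	0.20543916
53	0.20390778
54	0.20245249
55	0.20106682
56	0.19974501
57	0.19848186
58	0.19727271
59	0.19611335
60	0.195
61	0.19392922
62	0.19289789
63	0.19190321
64	0.19094261
65	0.19001376
66	0.18911452
67	0.18824295
68	0.18739728
69	0.18657587
70	0.18577723
71	0.18499999
72	0.18424289
73	0.18350476
74	0.18278453
75	0.18208121
76	0.18139388
77	0.18072171
78	0.18006389
79	0.1794197
80	0.17878848
81	0.17816957
82	0.17756241
83	0.17696644
84	0.17638115
85	0.17580607
86	0.17524076
87	0.17468479
88	0.17413777
89	0.17359934
90	0.17306916
91	0.17254691
92	0.17203227
93	0.17152497
94	0.17102473
95	0.17053131
96	0.17004446
97	0.16956396
98	0.16908959
99	0.16862115
100	0.16815845
101	0.16770131
102	0.16724955
103	0.16680302
104	0.16636156
105	0.16592501
106	0.16549325
107	0.16506613
108	0.16464354
109	0.16422534
110	0.16381143
111	0.16340168
112	0.16299601
113	0.1625943
114	0.16219646
115	0.1618024
116	0.16141202
117	0.16102525
118	0.160642
119	0.1602622
120	0.15988577
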