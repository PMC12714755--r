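# material: aluminum
# density_g_cm3: 2.699
energy_keV	mu_over_rho
10	26.290186
11	19.797345
12	15.290497
13	12.064768
14	9.6953963
15	7.916012
16	6.5537946
17	5.4932812
18	4.6553309
19	3.9844631
20	3.441
21	2.9960547
22	2.6282569
23	2.3215664
24	2.0637846
25	1.8455222
26	1.6594728
27	1.4998931
28	1.3622261
29	1.2428249
30	1.1387474
31	1.0476027
32	0.96743384
33	0.89662887
34	0.83385193
35	0.77798952
36	0.72810857
37	0.68342318
38	0.64326824
39	0.60707834
40	0.57437074
41	0.54473159
42	0.51780476
43	0.49328264
44	0.47089858
45	0.45042073
46	0.43164676
47	0.41439967
48	0.39852407
49	0.38388322
50	0.37035645
51	0.35783702
52	0.34623024
53	0.33545195
54	0.32542715
55	0.31608887
56	0.30737719
57	0.29923839
58	0.29162417
59	0.2844911
60	0.2778
61	0.27151546
62	0.26560547
63	0.26004099
64	0.25479566
65	0.24984553
66	0.24516878
67	0.2407455
68	0.23655754
69	0.23258827
70	0.22882248
71	0.22524622
72	0.22184668
73	0.2186121
74	0.21553164
75	0.21259533
76	0.20979396
77	0.20711904
78	0.20456272
79	0.20211772
80	0.19977731
81	0.19753526
82	0.19538578
83	0.19332349
84	0.19134338
85	0.1894408
86	0.18761142
87	0.1858512
88	0.18415637
89	0.18252341
90	0.18094903
91	0.17943015
92	0.17796389
93	0.17654757
94	0.17517865
95	0.17385475
96	0.17257367
97	0.1713333
98	0.17013167
99	0.16896695
100	0.1678374
101	0.16674137
102	0.16567732
103	0.1646438
104	0.16363943
105	0.16266291
106	0.16171303
107	0.16078862
108	0.15988859
109	0.15901191
110	0.15815758
111	0.15732469
112	0.15651235
113	0.15571972
114	0.15494603
115	0.1541905
116	0.15345243
117	0.15273115
118	0.15202599
119	0.15133636
120	0.15066167
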