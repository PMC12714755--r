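# material: pmma
# density_g_cm3: 1.19
energy_keV	mu_over_rho
10	3.1614781
11	2.4266724
12	1.9164199
13	1.5510237
14	1.2824581
15	1.0806058
16	0.92592671
17	0.80536603
18	0.70997555
19	0.63348229
20	0.5714
21	0.52046249
22	0.47825343
23	0.44295918
24	0.41320041
25	0.38791545
26	0.36627814
27	0.34763902
28	0.33148278
29	0.31739702
30	0.30504903
31	0.29416839
32	0.28453379
33	0.2759629
34	0.26830462
35	0.26143298
36	0.25524243
37	0.24964404
38	0.24456255
39	0.23993398
40	0.23570369
41	0.23182482
42	0.22825705
43	0.22496554
44	0.2219201
45	0.21909445
46	0.21646566
47	0.21401368
48	0.21172086
49	0.20957172
50	0.20755255
51	0.20565123
52	0.20385702
53	0.20216033
54	0.20055266
55	0.19902638
56	0.19757468
57	0.19619142
58	0.19487111
59	0.1936088
60	0.1924
61	0.19124068
62	0.19012718
63	0.18905616
64	0.18802461
65	0.18702979
66	0.18606918
67	0.1851405
68	0.18424166
69	0.18337073
70	0.18252597
71	0.18170575
72	0.1809086
73	0.18013315
74	0.17937815
75	0.17864241
76	0.17792489
77	0.17722457
78	0.17654055
79	0.17587196
80	0.17521801
81	0.17457797
82	0.17395116
83	0.17333692
84	0.17273468
85	0.17214386
86	0.17156396
87	0.17099448
88	0.17043498
89	0.16988503
90	0.16934422
91	0.16881219
92	0.16828858
93	0.16777306
94	0.16726531
95	0.16676505
96	0.166272
97	0.1657859
98	0.16530649
99	0.16483356
100	0.16436686
101	0.16390621
102	0.16345139
103	0.16300223
104	0.16255854
105	0.16212016
106	0.16168692
107	0.16125867
108	0.16083527
109	0.16041658
110	0.16000247
111	0.15959281
112	0.15918748
113	0.15878637
114	0.15838936
115	0.15799636
116	0.15760726
117	0.15722197
118	0.15684039
119	0.15646244
120	0.15608803
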