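# material: water
# density_g_cm3: 1
energy_keV	mu_over_rho
10	5.0285679
11	3.830849
12	2.9992846
13	2.40392
14	1.9664443
15	1.6377478
16	1.3859683
17	1.1898185
18	1.0347074
19	0.91040638
20	0.8096
21	0.72696251
22	0.65855387
23	0.60141677
24	0.55330212
25	0.51247882
26	0.47759973
27	0.44760592
28	0.42165715
29	0.39908102
30	0.37933504
31	0.36197831
32	0.34665
33	0.33305286
34	0.32094053
35	0.31010766
36	0.30038217
37	0.2916191
38	0.28369577
39	0.27650788
40	0.26996638
41	0.26399491
42	0.25852775
43	0.25350815
44	0.24888688
45	0.24462115
46	0.24067361
47	0.23701156
48	0.23360632
49	0.23043263
50	0.22746819
51	0.22469326
52	0.22209036
53	0.21964392
54	0.21734005
55	0.21516638
56	0.21311182
57	0.2111664
58	0.2093212
59	0.20756815
60	0.2059
61	0.20431017
62	0.20279273
63	0.20134228
64	0.19995392
65	0.1986232
66	0.19734605
67	0.19611878
68	0.194938
69	0.1938006
70	0.19270375
71	0.19164484
72	0.19062148
73	0.18963145
74	0.18867274
75	0.18774347
76	0.18684191
77	0.18596646
78	0.18511564
79	0.18428809
80	0.18348252
81	0.18269777
82	0.18193273
83	0.18118638
84	0.18045778
85	0.17974603
86	0.1790503
87	0.17836984
88	0.17770391
89	0.17705184
90	0.17641299
91	0.17578678
92	0.17517264
93	0.17457006
94	0.17397854
95	0.17339762
96	0.17282687
97	0.17226588
98	0.17171425
99	0.17117164
100	0.17063769
101	0.17011208
102	0.1695945
103	0.16908467
104	0.1685823
105	0.16808714
106	0.16759894
107	0.16711747
108	0.1666425
109	0.16617382
110	0.16571123
111	0.16525455
112	0.16480358
113	0.16435815
114	0.16391811
115	0.16348329
116	0.16305354
117	0.16262872
118	0.16220869
119	0.16179332
120	0.16138249
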