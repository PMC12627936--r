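# synthetic Gompertz-Makeham annual mortality (national-table style stand-in)
age	qx
0	0.0002249746894
1	0.0002274655972
2	0.0002302047388
3	0.0002332168514
4	0.0002365291373
5	0.0002401715091
6	0.0002441768603
7	0.0002485813616
8	0.0002534247880
9	0.0002587508777
10	0.0002646077267
11	0.0002710482229
12	0.0002781305237
13	0.0002859185805
14	0.0002944827161
15	0.0003039002590
16	0.0003142562410
17	0.0003256441645
18	0.0003381668456
19	0.0003519373417
20	0.0003670799707
21	0.0003837314320
22	0.0004020420385
23	0.0004221770720
24	0.0004443182716
25	0.0004686654717
26	0.0004954384011
27	0.0005248786622
28	0.0005572519049
29	0.0005928502174
30	0.0006319947531
31	0.0006750386185
32	0.0007223700459
33	0.0007744158812
34	0.0008316454154
35	0.0008945745954
36	0.0009637706500
37	0.0010398571715
38	0.0011235196990
39	0.0012155118492
40	0.0013166620512
41	0.0014278809406
42	0.0015501694782
43	0.0016846278626
44	0.0018324653119
45	0.0019950107980
46	0.0021737248234
47	0.0023702123388
48	0.0025862369078
49	0.0028237362359
50	0.0030848391887
51	0.0033718844361
52	0.0036874408696
53	0.0040343299524
54	0.0044156501738
55	0.0048348037905
56	0.0052955260542
57	0.0058019171343
58	0.0063584769598
59	0.0069701432177
60	0.0076423327570
61	0.0083809866596
62	0.0091926192481
63	0.0100843713105
64	0.0110640678257
65	0.0121402804716
66	0.0133223951993
67	0.0146206851377
68	0.0160463890791
69	0.0176117957595
70	0.0193303341064
71	0.0212166695594
72	0.0232868064906
73	0.0255581966360
74	0.0280498533139
75	0.0307824710227
76	0.0337785497894
77	0.0370625233617
78	0.0406608899936
79	0.0446023441599
80	0.0489179070317
81	0.0536410529386
82	0.0588078283287
83	0.0644569588846
84	0.0706299394610
85	0.0773711003559
86	0.0847276420995
87	0.0927496294392
88	0.1014899335102
89	0.1110041093127
90	0.1213501936001
91	0.1325884061429
92	0.1447807351502
93	0.1579903854901
94	0.1722810664071
95	0.1877160938757
96	0.2043572818228
97	0.2222635965367
98	0.2414895500931
99	0.2620833120934
100	0.2840845250540
101	0.3075218181409
102	0.3324100273735
103	0.3587471487440
104	0.3865110746305
105	0.4156561939677
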