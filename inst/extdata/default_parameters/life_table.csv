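"age","qx"
30,0.00055
31,0.000603000652144449
32,0.000661108702702966
33,0.000724816325215017
34,0.000794663121435633
35,0.000871240691746965
36,0.000955197645996729
37,0.00104724509720522
38,0.00114816268467241
39,0.0012588051775007
40,0.00138010971446496
41,0.00151310374155139
42,0.00165891371439581
43,0.00181877463933098
44,0.00199404053385522
45,0.00218619589512211
46,0.00239686827358937
47,0.00262784205832496
48,0.00288107359073193
49,0.00315870773470456
50,0.00346309604356466
51,0.00379681667765155
52,0.00416269624126692
53,0.00456383372393309
54,0.00500362674874634
55,0.0054858003501481
56,0.006014438524861
57,0.00659401882322524
58,0.0072294502739229
59,0.0079261149633116
60,0.00868991362154322
61,0.0095273156015809
62,0.010445413674435
63,0.0114519841047325
64,0.0125555525154574
65,0.0137654660997358
66,0.0150919727912963
67,0.0165463080641782
68,0.0181407900968771
69,0.0198889241069681
70,0.0218055167399149
71,0.0239068014809371
72,0.026210576152169
73,0.0287363536597085
74,0.0315055272673777
75,0.0345415517970609
76,0.03787014229038
77,0.0415194918143677
78,0.0455205102559452
79,0.0499070861277874
80,0.0547163736030636
81,0.0599891072102303
82,0.0657699468533312
83,0.0721078560801173
84,0.079056516801907
85,0.0866747839778518
86,0.0950271841147708
87,0.104184461804832
88,0.11422417893024
89,0.12523137161018
90,0.137299270454332
91,0.150530090223489
92,0.165035895585685
93,0.180939550300748
94,0.198375757872863
95,0.217492202485428
96,0.238450799881901
97,0.261429068787549
98,0.286621634488015
99,0.314241877299966
100,0.344523739896319
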