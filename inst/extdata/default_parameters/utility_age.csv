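"age","utility"
30,0.9132156
31,0.9109317
32,0.9085814
33,0.9061647
34,0.9036816
35,0.9011321
36,0.8985162
37,0.8958339
38,0.8930852
39,0.8902701
40,0.8873886
41,0.8844407
42,0.8814264
43,0.8783457
44,0.8751986
45,0.8719851
46,0.8687052
47,0.8653589
48,0.8619462
49,0.8584671
50,0.8549216
51,0.8513097
52,0.8476314
53,0.8438867
54,0.8400756
55,0.8361981
56,0.8322542
57,0.8282439
58,0.8241672
59,0.8200241
60,0.8158146
61,0.8115387
62,0.8071964
63,0.8027877
64,0.7983126
65,0.7937711
66,0.7891632
67,0.7844889
68,0.7797482
69,0.7749411
70,0.7700676
71,0.7651277
72,0.7601214
73,0.7550487
74,0.7499096
75,0.7447041
76,0.7394322
77,0.7340939
78,0.7286892
79,0.7232181
80,0.7176806
81,0.7120767
82,0.7064064
83,0.7006697
84,0.6948666
85,0.6889971
86,0.6830612
87,0.6770589
88,0.6709902
89,0.6648551
90,0.6586536
91,0.6523857
92,0.6460514
93,0.6396507
94,0.6331836
95,0.6266501
96,0.6200502
97,0.6133839
98,0.6066512
99,0.5998521
100,0.5929866
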