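"age_lo","age_hi","p"
30,39,0.000102511686001886
40,44,0.000307535058005658
45,49,0.000717581802013201
50,54,0.00123014023202263
55,59,0.00174269866203206
60,64,0.00205023372003772
65,69,0.00174269866203206
70,79,0.00112762854602075
80,100,0.000717581802013201
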