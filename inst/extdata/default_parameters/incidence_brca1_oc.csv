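"age_lo","age_hi","p"
30,34,0.0020728924048882
35,39,0.0062186772146646
40,44,0.010364462024441
45,49,0.0165831392391056
50,54,0.020728924048882
55,59,0.020728924048882
60,64,0.0165831392391056
65,69,0.0124373544293292
70,79,0.0082915696195528
80,100,0.0051822310122205
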