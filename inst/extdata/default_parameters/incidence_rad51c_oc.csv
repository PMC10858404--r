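"age_lo","age_hi","p"
30,44,0.00022809726036674
45,49,0.0011404863018337
50,59,0.0034214589055011
60,69,0.0045619452073348
70,79,0.00273716712440088
80,100,0.00159668082256718
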