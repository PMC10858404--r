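"age_lo","age_hi","p"
30,34,0.00752244492539751
35,39,0.0165493788358745
40,49,0.0255763127463515
50,59,0.0255763127463515
60,69,0.0225673347761925
70,79,0.018053867820954
80,100,0.012035911880636
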