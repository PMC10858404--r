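"age_lo","age_hi","p"
30,39,0.000123058530967352
40,49,0.000430704858385734
50,59,0.00098446824773882
60,69,0.00184587796451029
70,79,0.00246117061934705
80,100,0.00196893649547764
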