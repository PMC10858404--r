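"age_lo","age_hi","p"
30,34,0.00554773395797237
35,39,0.0110954679159447
40,49,0.0177527486655116
50,59,0.0188622954571061
60,69,0.0166432018739171
70,79,0.0133145614991337
80,100,0.00887637433275579
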