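"age_lo","age_hi","p"
30,39,3.60875457382265e-05
40,49,0.000126306410083793
50,59,0.000288700365905812
60,69,0.000541313186073398
70,79,0.000721750914764531
80,100,0.000577400731811625
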