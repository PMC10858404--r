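"age_lo","age_hi","p"
30,44,0.000272491140767182
45,49,0.00136245570383591
50,59,0.00408736711150773
60,69,0.00544982281534364
70,79,0.00326989368920619
80,100,0.00190743798537028
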