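"age_lo","age_hi","p"
30,39,0.00119225240551139
40,49,0.00357675721653416
50,59,0.00556384455905313
60,69,0.00675609696456452
70,79,0.00516642709054934
80,100,0.00357675721653416
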