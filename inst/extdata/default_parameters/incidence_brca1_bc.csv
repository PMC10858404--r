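"age_lo","age_hi","p"
30,34,0.0128554980671472
35,39,0.0257109961342944
40,49,0.032138745167868
50,59,0.0257109961342944
60,69,0.0208901843591142
70,79,0.016069372583934
80,100,0.0112485608087538
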