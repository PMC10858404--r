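"age_lo","age_hi","p"
30,39,0.00125927279352139
40,49,0.00377781838056416
50,59,0.00587660636976647
60,69,0.00713587916328785
70,79,0.00545684877192601
80,100,0.00377781838056416
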