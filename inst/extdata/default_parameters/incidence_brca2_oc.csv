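"age_lo","age_hi","p"
30,39,0.000403922727555012
40,44,0.00161569091022005
45,49,0.00323138182044009
50,54,0.00525099545821515
55,59,0.00727060909599021
60,64,0.00807845455110023
65,69,0.00646276364088019
70,79,0.00403922727555012
80,100,0.00242353636533007
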