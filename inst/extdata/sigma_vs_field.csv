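x,value
10000,0.065000
20000,0.071170
30000,0.086596
40000,0.106650
50000,0.126704
60000,0.142130
70000,0.148300
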