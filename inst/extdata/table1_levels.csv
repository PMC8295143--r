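factor,level1,level2,level3
active_length_mm,10,15,
distance_mm,10,15,20
voltage_V,1000,2000,3000
pulse_number,30,60,90
pulse_width_us,40,70,100
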