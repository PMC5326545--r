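site,area_m2,depth_min,depth_max
D1,1184,20,30
D2,1800,15,30
D3,1470,20,30
D4,1800,15,30
D5,1800,15,30
D6,1800,19,35
D7,1650,20,35
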