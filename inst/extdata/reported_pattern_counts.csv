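pattern,normal,PPG,PG
diffuse,0,10,24
wedge,4,12,11
other_grouping,13,4,0
isolated,6,3,0
none,12,1,0
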