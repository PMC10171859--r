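animal,early_active,chronic_demyelinated,remyelinated
M1,1,2,6
M2,1,1,6
M3,1,1,4
M4,0,1,2
M5,3,3,0
M6,6,2,0
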