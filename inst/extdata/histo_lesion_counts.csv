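animal,early_active,chronic_demyelinated,remyelinated
M2,1,3,4
M3,1,1,4
M4,0,2,1
M5,3,3,0
M6,7,1,0
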