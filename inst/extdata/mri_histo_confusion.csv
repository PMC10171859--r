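cell,count
tp,9
fn,0
fp,3
tn,19
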