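whitelist,read_index,start,read_fraction
bc1,1,1,1
bc2,1,15,1
bc3,1,29,1
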