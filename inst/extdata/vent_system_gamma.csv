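system,gamma,extent_km
backarc,39,599
arc,45,1107
jdf,71,565
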