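name,C,H,N,O
hex,6,10,0,5
hexnac,8,13,1,5
fuc,6,10,0,4
neuac,11,17,1,8
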