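name,hex,hexnac,fuc,neuac,rt_offset_min,rt_resolved
M5,5,2,0,0,-1.5,FALSE
A1G0F,3,3,1,0,-1.5,FALSE
A2G0F,3,4,1,0,-1.5,FALSE
A1G1F,4,3,1,0,-1.5,FALSE
A2G1F,4,4,1,0,-1.5,FALSE
A2G2F,5,4,1,0,-1.5,FALSE
A2Ga1G1F,5,4,1,0,-0.7,TRUE
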