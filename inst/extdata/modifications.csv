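name,targets,dC,dH,dN,dO,dS,rt_offset_min,rt_resolved,terminal
deamidation,N,0,-1,-1,1,0,0.4,FALSE,none
oxidation,MW,0,0,0,1,0,-1.2,FALSE,none
succinimide,N,0,-3,-1,0,0,0.6,FALSE,none
NH3 loss,NQ,0,-3,-1,0,0,0.5,FALSE,none
H2O loss,DST,0,-2,0,-1,0,0.6,FALSE,none
Gln->PyroGlu,Q,0,-3,-1,0,0,0.5,FALSE,peptide_n
Lys loss,K,-6,-12,-2,-1,0,-0.5,FALSE,chain_c
isomerisation,DN,0,0,0,0,0,0.8,TRUE,none
Trp->oxolactone,W,0,-2,0,1,0,-0.8,FALSE,none
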