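letter,name,C,H,N,O,S,mono_mass,rt_coef
G,Glycine,2,3,1,1,0,57.021464,-0.4
A,Alanine,3,5,1,1,0,71.037114,1.8
S,Serine,3,5,1,2,0,87.032028,-0.8
P,Proline,5,7,1,1,0,97.052764,-1.6
V,Valine,5,9,1,1,0,99.068414,4.2
T,Threonine,4,7,1,2,0,101.047679,-0.7
C,Cysteine,3,5,1,1,1,103.009185,2.5
L,Leucine,6,11,1,1,0,113.084064,3.8
I,Isoleucine,6,11,1,1,0,113.084064,4.5
N,Asparagine,4,6,2,2,0,114.042927,-3.5
D,Aspartate,4,5,1,3,0,115.026943,-3.5
Q,Glutamine,5,8,2,2,0,128.058578,-3.5
K,Lysine,6,12,2,1,0,128.094963,-3.9
E,Glutamate,5,7,1,3,0,129.042593,-3.5
M,Methionine,5,9,1,1,1,131.040485,1.9
H,Histidine,6,7,3,1,0,137.058912,-3.2
F,Phenylalanine,9,9,1,1,0,147.068414,2.8
R,Arginine,6,12,4,1,0,156.101111,-4.5
Y,Tyrosine,9,9,1,2,0,163.063329,-1.3
W,Tryptophan,11,10,2,1,0,186.079313,-0.9
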