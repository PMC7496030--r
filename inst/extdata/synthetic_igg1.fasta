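>HC synthetic IgG1-like heavy chain (toy construct for tests and demos)
QVTLRDTLMISRTKPREEQYNSTYRGFYPSDIAVEWESNGQPENNYKVVSVLTVLHQDWLN
GKFNWYVDGVEVHNAKWQQGNVFSCSVMHEALHNHYTQKSLSLSPGK
>LC synthetic IgG1-like light chain (toy construct for tests and demos)
DIQMTQSPSSLSASVGDRASQDINNYLNWYQQKPGKASQDVDTAVAWYQQKPGKLLIYWAS
TR
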