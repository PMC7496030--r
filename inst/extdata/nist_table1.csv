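attribute,mode,site_label,sequence,mc_partner,modification,ireland,denmark,uk,switzerland
HC N328+Deam,pairwise,HC N328,VSNKALPAPIEK,,deamidation,0.30,0.50,0.33,0.50
HC N364+Deam,pairwise,HC N364,NQVSLTCLVK,,deamidation,0.37,0.20,0.29,0.05
HC~N392/N387+Deam,pairwise,HC~N392/N387,GFYPSDIAVEWESNGQPENNYK,,deamidation,0.79,0.21,0.24,0.64
HC~N392/N387+Succ,pairwise,HC~N392/N387,GFYPSDIAVEWESNGQPENNYK,,succinimide,2.06,2.27,2.73,2.60
HC N318+Succ,pairwise,HC N318,VVSVLTVLHQDWLNGK,,succinimide,2.05,2.61,2.66,2.25
HC D283+Succ,pairwise,HC D283,FNWYVDGVEVHNAK,,H2O loss,2.18,3.40,1.56,3.56
HC M255+Oxid,pairwise,HC M255,DTLMISR,,oxidation,1.26,1.29,1.05,0.92
HC K450 Lys loss,pairwise,HC K450,SLSLSPGK,WQQGNVFSCSVMHEALHNHYTQKSLSLSPGK,Lys loss,87.01,88.49,90.73,88.79
HC Q1+Gln->PyroGlu,pairwise,HC Q1,QVTLR,,Gln->PyroGlu,99.29,99.31,99.75,99.32
HC N300+M5,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,M5,1.71,1.29,1.10,1.22
HC N300+A1G0F,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,A1G0F,6.05,5.04,11.26,10.95
HC N300+A2G0F,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,A2G0F,41.13,40.14,37.36,37.05
HC N300+A1G1F,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,A1G1F,4.06,3.68,5.92,6.13
HC N300+A2G1F,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,A2G1F,36.11,38.65,33.86,34.89
HC N300+A2G2F,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,A2G2F,6.92,8.49,7.02,7.31
HC N300+A2Ga1G1F,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,A2Ga1G1F,0.91,1.42,1.09,1.21
HC N300+unglycos,profile,HC N300,EEQYNSTYR,TKPREEQYNSTYR,unglycosylated,3.06,1.29,2.39,1.25
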