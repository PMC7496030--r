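attribute,sequence,modification,site,months,value,rsd
mAb4_HC N101+deamidation,KGNYGNYGK,deamidation,A,0,6.02,1.81
mAb4_HC N101+deamidation,KGNYGNYGK,deamidation,A,3,18.81,3.33
mAb4_HC N101+deamidation,KGNYGNYGK,deamidation,A,6,21.61,1.37
mAb4_HC N101+deamidation,KGNYGNYGK,deamidation,B,0,4.81,5.57
mAb4_HC N101+deamidation,KGNYGNYGK,deamidation,B,3,16.04,5.12
mAb4_HC N101+deamidation,KGNYGNYGK,deamidation,B,6,24.23,3.35
mAb6_LC~N30+deamidation,ASQDINNYLNWYQQKPGK,deamidation,A,0,1.27,7.54
mAb6_LC~N30+deamidation,ASQDINNYLNWYQQKPGK,deamidation,A,3,28.08,1.14
mAb6_LC~N30+deamidation,ASQDINNYLNWYQQKPGK,deamidation,A,6,44.68,1.40
mAb6_LC~N30+deamidation,ASQDINNYLNWYQQKPGK,deamidation,B,0,0.46,8.08
mAb6_LC~N30+deamidation,ASQDINNYLNWYQQKPGK,deamidation,B,3,25.52,0.67
mAb6_LC~N30+deamidation,ASQDINNYLNWYQQKPGK,deamidation,B,6,43.65,0.16
mAb1_HC~N389+deamidation,GFYPSDIAVEWESNGQPENNYK,deamidation,A,0,1.66,6.33
mAb1_HC~N389+deamidation,GFYPSDIAVEWESNGQPENNYK,deamidation,A,3,2.54,7.91
mAb1_HC~N389+deamidation,GFYPSDIAVEWESNGQPENNYK,deamidation,A,6,3.28,8.33
mAb1_HC~N389+deamidation,GFYPSDIAVEWESNGQPENNYK,deamidation,B,0,0.19,7.41
mAb1_HC~N389+deamidation,GFYPSDIAVEWESNGQPENNYK,deamidation,B,3,0.44,5.78
mAb1_HC~N389+deamidation,GFYPSDIAVEWESNGQPENNYK,deamidation,B,6,0.69,3.70
mAb1_HC~N384+NH3 loss,GFYPSDIAVEWESNGQPENNYK,NH3 loss,A,0,1.70,5.48
mAb1_HC~N384+NH3 loss,GFYPSDIAVEWESNGQPENNYK,NH3 loss,A,3,1.99,3.84
mAb1_HC~N384+NH3 loss,GFYPSDIAVEWESNGQPENNYK,NH3 loss,A,6,1.98,2.30
mAb1_HC~N384+NH3 loss,GFYPSDIAVEWESNGQPENNYK,NH3 loss,B,0,0.33,3.99
mAb1_HC~N384+NH3 loss,GFYPSDIAVEWESNGQPENNYK,NH3 loss,B,3,0.34,4.26
mAb1_HC~N384+NH3 loss,GFYPSDIAVEWESNGQPENNYK,NH3 loss,B,6,0.30,5.57
mAb1_HC N315+deamidation,VVSVLTVLHQDWLNGK,deamidation,A,0,0.96,0.52
mAb1_HC N315+deamidation,VVSVLTVLHQDWLNGK,deamidation,A,3,1.19,4.25
mAb1_HC N315+deamidation,VVSVLTVLHQDWLNGK,deamidation,A,6,1.48,1.88
mAb1_HC N315+deamidation,VVSVLTVLHQDWLNGK,deamidation,B,0,0.65,6.29
mAb1_HC N315+deamidation,VVSVLTVLHQDWLNGK,deamidation,B,3,0.70,3.99
mAb1_HC N315+deamidation,VVSVLTVLHQDWLNGK,deamidation,B,6,0.61,3.79
mAb1_HC N315+NH3 loss,VVSVLTVLHQDWLNGK,NH3 loss,A,0,3.89,4.69
mAb1_HC N315+NH3 loss,VVSVLTVLHQDWLNGK,NH3 loss,A,3,4.31,3.43
mAb1_HC N315+NH3 loss,VVSVLTVLHQDWLNGK,NH3 loss,A,6,4.59,6.29
mAb1_HC N315+NH3 loss,VVSVLTVLHQDWLNGK,NH3 loss,B,0,2.67,4.28
mAb1_HC N315+NH3 loss,VVSVLTVLHQDWLNGK,NH3 loss,B,3,2.68,4.09
mAb1_HC N315+NH3 loss,VVSVLTVLHQDWLNGK,NH3 loss,B,6,2.47,2.98
mAb2_LC~D30+isomerisation,ASQDVDTAVAWYQQKPGK,isomerisation,A,0,3.42,3.96
mAb2_LC~D30+isomerisation,ASQDVDTAVAWYQQKPGK,isomerisation,A,3,47.75,3.63
mAb2_LC~D30+isomerisation,ASQDVDTAVAWYQQKPGK,isomerisation,A,6,45.92,1.43
mAb2_LC~D30+isomerisation,ASQDVDTAVAWYQQKPGK,isomerisation,B,0,2.33,5.63
mAb2_LC~D30+isomerisation,ASQDVDTAVAWYQQKPGK,isomerisation,B,3,40.66,1.08
mAb2_LC~D30+isomerisation,ASQDVDTAVAWYQQKPGK,isomerisation,B,6,NA,NA
mAb2_LC~D30+H2O loss,ASQDVDTAVAWYQQKPGK,H2O loss,A,0,0.16,5.79
mAb2_LC~D30+H2O loss,ASQDVDTAVAWYQQKPGK,H2O loss,A,3,2.14,3.50
mAb2_LC~D30+H2O loss,ASQDVDTAVAWYQQKPGK,H2O loss,A,6,2.03,4.38
mAb2_LC~D30+H2O loss,ASQDVDTAVAWYQQKPGK,H2O loss,B,0,0.13,9.86
mAb2_LC~D30+H2O loss,ASQDVDTAVAWYQQKPGK,H2O loss,B,3,2.52,2.81
mAb2_LC~D30+H2O loss,ASQDVDTAVAWYQQKPGK,H2O loss,B,6,2.83,0.48
mAb1_HC D280+isomerisation,FNWYVDGVEVHNAK,isomerisation,A,0,0.73,6.71
mAb1_HC D280+isomerisation,FNWYVDGVEVHNAK,isomerisation,A,3,6.06,2.11
mAb1_HC D280+isomerisation,FNWYVDGVEVHNAK,isomerisation,A,6,9.59,2.86
mAb1_HC D280+isomerisation,FNWYVDGVEVHNAK,isomerisation,B,0,0.57,3.32
mAb1_HC D280+isomerisation,FNWYVDGVEVHNAK,isomerisation,B,3,4.71,3.71
mAb1_HC D280+isomerisation,FNWYVDGVEVHNAK,isomerisation,B,6,7.74,2.55
mAb1_HC D280+H2O loss,FNWYVDGVEVHNAK,H2O loss,A,0,0.06,3.63
mAb1_HC D280+H2O loss,FNWYVDGVEVHNAK,H2O loss,A,3,0.17,4.71
mAb1_HC D280+H2O loss,FNWYVDGVEVHNAK,H2O loss,A,6,0.18,2.00
mAb1_HC D280+H2O loss,FNWYVDGVEVHNAK,H2O loss,B,0,0.22,2.97
mAb1_HC D280+H2O loss,FNWYVDGVEVHNAK,H2O loss,B,3,0.37,1.11
mAb1_HC D280+H2O loss,FNWYVDGVEVHNAK,H2O loss,B,6,0.35,3.12
mAb1_HC M252+oxidation,DTLMISR,oxidation,A,0,3.40,2.25
mAb1_HC M252+oxidation,DTLMISR,oxidation,A,3,5.93,3.19
mAb1_HC M252+oxidation,DTLMISR,oxidation,A,6,5.82,2.20
mAb1_HC M252+oxidation,DTLMISR,oxidation,B,0,2.81,5.04
mAb1_HC M252+oxidation,DTLMISR,oxidation,B,3,4.94,2.19
mAb1_HC M252+oxidation,DTLMISR,oxidation,B,6,5.59,1.84
mAb3_LC M4+oxidation,DIQMTQSPSSLSASVGDR,oxidation,A,0,1.79,7.23
mAb3_LC M4+oxidation,DIQMTQSPSSLSASVGDR,oxidation,A,3,2.46,6.82
mAb3_LC M4+oxidation,DIQMTQSPSSLSASVGDR,oxidation,A,6,1.77,3.75
mAb3_LC M4+oxidation,DIQMTQSPSSLSASVGDR,oxidation,B,0,0.06,19.61
mAb3_LC M4+oxidation,DIQMTQSPSSLSASVGDR,oxidation,B,3,0.09,5.89
mAb3_LC M4+oxidation,DIQMTQSPSSLSASVGDR,oxidation,B,6,0.09,8.60
mAb3_LC M48+oxidation,LLMYISR,oxidation,A,0,0.45,7.93
mAb3_LC M48+oxidation,LLMYISR,oxidation,A,3,0.59,6.12
mAb3_LC M48+oxidation,LLMYISR,oxidation,A,6,0.582,1.70
mAb3_LC M48+oxidation,LLMYISR,oxidation,B,0,NA,NA
mAb3_LC M48+oxidation,LLMYISR,oxidation,B,3,NA,NA
mAb3_LC M48+oxidation,LLMYISR,oxidation,B,6,NA,NA
mAb1_HC M428+oxidation,WQQGNVFSCSVMHEALHNHYTQK,oxidation,A,0,1.87,6.04
mAb1_HC M428+oxidation,WQQGNVFSCSVMHEALHNHYTQK,oxidation,A,3,2.35,4.69
mAb1_HC M428+oxidation,WQQGNVFSCSVMHEALHNHYTQK,oxidation,A,6,2.38,12.20
mAb1_HC M428+oxidation,WQQGNVFSCSVMHEALHNHYTQK,oxidation,B,0,1.16,6.90
mAb1_HC M428+oxidation,WQQGNVFSCSVMHEALHNHYTQK,oxidation,B,3,1.91,3.68
mAb1_HC M428+oxidation,WQQGNVFSCSVMHEALHNHYTQK,oxidation,B,6,2.27,3.21
mAb2_LC W50+oxidation,LLIYWASTR,oxidation,A,0,0.18,2.80
mAb2_LC W50+oxidation,LLIYWASTR,oxidation,A,3,0.55,0.38
mAb2_LC W50+oxidation,LLIYWASTR,oxidation,A,6,0.87,7.23
mAb2_LC W50+oxidation,LLIYWASTR,oxidation,B,0,0.24,5.37
mAb2_LC W50+oxidation,LLIYWASTR,oxidation,B,3,0.70,8.58
mAb2_LC W50+oxidation,LLIYWASTR,oxidation,B,6,1.01,4.93
mAb1_LC M4+oxidation,DVVMTQSPLSLPVTLGQPASISCR,oxidation,A,0,1.85,2.51
mAb1_LC M4+oxidation,DVVMTQSPLSLPVTLGQPASISCR,oxidation,A,3,5.04,1.96
mAb1_LC M4+oxidation,DVVMTQSPLSLPVTLGQPASISCR,oxidation,A,6,5.20,9.02
mAb1_LC M4+oxidation,DVVMTQSPLSLPVTLGQPASISCR,oxidation,B,0,0.56,4.53
mAb1_LC M4+oxidation,DVVMTQSPLSLPVTLGQPASISCR,oxidation,B,3,3.26,1.56
mAb1_LC M4+oxidation,DVVMTQSPLSLPVTLGQPASISCR,oxidation,B,6,3.63,1.15
mAb2_HC W33+oxolactone,ASGYTFTSYWMQWVR,Trp->oxolactone,A,0,0.20,3.94
mAb2_HC W33+oxolactone,ASGYTFTSYWMQWVR,Trp->oxolactone,A,3,3.97,6.33
mAb2_HC W33+oxolactone,ASGYTFTSYWMQWVR,Trp->oxolactone,A,6,6.18,0.64
mAb2_HC W33+oxolactone,ASGYTFTSYWMQWVR,Trp->oxolactone,B,0,0.35,4.06
mAb2_HC W33+oxolactone,ASGYTFTSYWMQWVR,Trp->oxolactone,B,3,6.89,20.13
mAb2_HC W33+oxolactone,ASGYTFTSYWMQWVR,Trp->oxolactone,B,6,12.17,5.54
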