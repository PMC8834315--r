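rank,compound_id,name,smiles,binding_energy,binding_efficiency,role
1,DB00378,Dydrogesterone,CC(=O)C1CCC2C1(C)CCC1C2C=CC2=CC(=O)CCC12C,-12.6,-0.548,candidate
2,DB06710,Methyltestosterone,CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2(C)O,-11.6,-0.527,candidate
3,DB04575,Quinestrol,C#CC1(O)CCC2C1(C)CCC1c3ccc(OC4CCCC4)cc3CCC21,-11.6,-0.43,candidate
4,DB09280,Lumacaftor,Cc1ccc(NC(=O)C2(c3ccc4c(c3)OC(F)(F)O4)CC2)nc1-c1cccc(C(=O)O)c1,-12.1,-0.367,candidate
5,DB00984,Nandrolone phenpropionate,CC12CCC3C(CCC4=CC(=O)CCC34)C1CCC2OC(=O)CCc1ccccc1,-11.6,-0.387,candidate
6,DB05812,Abiraterone,CC12CCC(O)CC1=CCC1C2CCC2(C)C1CC=C2c1cccnc1,-11.4,-0.438,candidate
7,DB06210,Eltrombopag,Cc1ccc(N2N=C(C)C(=NNc3cccc(-c4cccc(C(=O)O)c4)c3O)C2=O)cc1C,-11.4,-0.345,candidate
8,DB00977,Ethinyl Estradiol,C#CC1(O)CCC2C1(C)CCC1c3ccc(O)cc3CCC21,-11.3,-0.514,candidate
9,DB01420,Testosterone propionate,CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2OC(=O)CC,-11.3,-0.452,candidate
10,DB12598,Nafamostat,NC(=N)c1ccc2cc(OC(=O)c3ccc(NC(=N)N)cc3)ccc2c1,-11.3,-0.435,candidate
11,DB04540,Cholesterol,CC(C)CCCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C,-11.3,-0.404,reference
12,DB04705,25-HC,CC(CCCC(C)(C)O)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C,-11.7,-0.403,reference
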