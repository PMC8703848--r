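id,smiles,charge,bbb,ccs,mw,psa,logd74,xlogp3
caffeine_like,CN1C=NC2=C1C(=O)N(C)C(=O)N2C,neutral,BBB+,142.1,194.2,58.4,-0.1,-0.1
diazepam_like,CN1C(=O)CN=C(C2=CC=CC=C2)C2=CC(Cl)=CC=C12,neutral,BBB+,168.8,284.7,32.7,2.8,2.8
morphine_like,CN1CCC23C4OC5=C(O)C=CC(CC1C2C=CC4O)=C35,positive,BBB+,164.5,285.3,52.9,0.9,0.8
ibuprofen_like,CC(C)CC1=CC=C(C=C1)C(C)C(=O)O,negative,BBB+,153.9,206.3,37.3,0.8,3.5
atenolol_like,CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1,positive,BBB-,171.2,266.3,84.6,-1.8,0.2
sulpiride_like,CCN1CCCC1CNC(=O)C1=CC(=CC=C1OC)S(N)(=O)=O,positive,BBB-,186.4,341.4,110.1,-1.1,0.6
loperamide_like,CN(C)C(=O)C(CCN1CCC(O)(CC1)C1=CC=C(Cl)C=C1)(C1=CC=CC=C1)C1=CC=CC=C1,positive,BBB-,221.6,477.0,43.8,2.8,4.8
unlabelled_probe,CCOC(=O)N1CCN(CC1)C(C)=O,neutral,unknown,n/a,200.2,49.9,0.3,0.3
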