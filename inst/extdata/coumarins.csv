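"no","mol_id","substituents","smiles","dpph_pct","lp_pct","lox_pct","ic50_um","log_lox","calc_eq2","split","outlier"
1,"A1","3-acetyl","O=C1C(C(C)=O)=Cc2ccccc2O1",16.3,23,18.5,NA,1.27,1.11,"train",FALSE
2,"A2","3-methoxycarbonyl","O=C1C(C(=O)OC)=Cc2ccccc2O1",32.1,16.6,7.1,NA,0.85,1.04,"train",FALSE
3,"A3","3-ethoxycarbonyl","O=C1C(C(=O)OCC)=Cc2ccccc2O1",33.5,7,14.3,NA,1.15,1.09,"train",FALSE
4,"A4","3-cyano","O=C1C(C#N)=Cc2ccccc2O1",36.4,NA,14.8,NA,1.17,1.37,"train",FALSE
5,"A5","3-benzoyl","O=C1C(C(=O)c3ccccc3)=Cc2ccccc2O1",31.1,42.1,22.5,NA,1.35,1.31,"train",FALSE
6,"C4","3-cyano; 7-benzoyl","O=C1C(C#N)=Cc2ccc(C(=O)c3ccccc3)cc2O1",32.1,57.9,33.9,NA,1.53,1.73,"train",FALSE
7,"C5","3-benzoyl; 7-benzyloxy","O=C1C(C(=O)c3ccccc3)=Cc2ccc(OCc3ccccc3)cc2O1",36.3,86.1,96.6,26.82,1.98,1.97,"train",FALSE
8,"COUM","","O=C1C=Cc2ccccc2O1",33.2,2.6,23.1,NA,1.36,1.31,"train",FALSE
9,"D1","3-acetyl; 8-hydroxy","O=C1C(C(C)=O)=Cc2cccc(O)c2O1",25.2,38,29.3,NA,1.47,1.49,"train",FALSE
10,"D4","3-cyano; 8-hydroxy","O=C1C(C#N)=Cc2cccc(O)c2O1",39.2,12.9,39.5,NA,1.6,1.74,"train",FALSE
11,"E1","3-acetyl; 7-hydroxy","O=C1C(C(C)=O)=Cc2ccc(O)cc2O1",15.9,29.8,45.1,NA,1.65,1.57,"train",FALSE
12,"E2","3-methoxycarbonyl; 7-hydroxy","O=C1C(C(=O)OC)=Cc2ccc(O)cc2O1",15.2,44.7,37.4,NA,1.57,1.51,"train",FALSE
13,"E5","3-benzoyl; 7-hydroxy","O=C1C(C(=O)c3ccccc3)=Cc2ccc(O)cc2O1",32.7,55.2,76.1,13.98,1.88,1.79,"train",FALSE
14,"F1","3-acetyl; 7-diethylamino","O=C1C(C(C)=O)=Cc2ccc(N(CC)CC)cc2O1",16.4,41.6,16.8,NA,1.22,NA,"train",TRUE
15,"G1","3-acetyl; 6-bromo","O=C1C(C(C)=O)=Cc2cc(Br)ccc2O1",21.2,70.6,11.3,NA,1.05,1.18,"train",FALSE
16,"G2","3-methoxycarbonyl; 6-bromo","O=C1C(C(=O)OC)=Cc2cc(Br)ccc2O1",28.4,86.6,85.1,61,1.93,1.4,"test",FALSE
17,"G3","3-ethoxycarbonyl; 6-bromo","O=C1C(C(=O)OCC)=Cc2cc(Br)ccc2O1",32.9,76.7,55.2,97.48,1.74,1.45,"train",FALSE
18,"G4","3-cyano; 6-bromo","O=C1C(C#N)=Cc2cc(Br)ccc2O1",48.4,81,84.8,64.77,1.93,1.77,"train",FALSE
19,"J1","3-acetyl; 6-hydroxy","O=C1C(C(C)=O)=Cc2cc(O)ccc2O1",22.5,69.2,48.5,NA,1.69,1.53,"test",FALSE
20,"J2","3-methoxycarbonyl; 6-hydroxy","O=C1C(C(=O)OC)=Cc2cc(O)ccc2O1",24,62.8,25.4,NA,1.4,1.49,"train",FALSE
21,"J3","3-ethoxycarbonyl; 6-hydroxy","O=C1C(C(=O)OCC)=Cc2cc(O)ccc2O1",58.1,47.1,51.9,17.4,1.71,1.54,"train",FALSE
22,"J4","3-cyano; 6-hydroxy","O=C1C(C#N)=Cc2cc(O)ccc2O1",39,66.8,29.3,NA,1.47,1.77,"test",FALSE
23,"J5","3-benzoyl; 6-hydroxy","O=C1C(C(=O)c3ccccc3)=Cc2cc(O)ccc2O1",38.9,66.5,55.4,88.55,1.74,1.77,"train",FALSE
24,"K3","3-ethoxycarbonyl; 6-chloro","O=C1C(C(=O)OCC)=Cc2cc(Cl)ccc2O1",31.2,64.4,47.6,NA,1.68,1.47,"test",FALSE
25,"K5","3-benzoyl; 6-chloro","O=C1C(C(=O)c3ccccc3)=Cc2cc(Cl)ccc2O1",32.1,58.1,37,NA,1.57,1.69,"test",FALSE
26,"L3","3-ethoxycarbonyl; 6-bromo; 8-bromo","O=C1C(C(=O)OCC)=Cc2cc(Br)cc(Br)c2O1",31.7,31.1,56.1,84.35,1.75,1.81,"train",FALSE
27,"M2","3-methoxycarbonyl; 7-methoxy","O=C1C(C(=O)OC)=Cc2ccc(OC)cc2O1",21,61.9,25.2,NA,1.4,1.56,"train",FALSE
28,"M3","3-ethoxycarbonyl; 7-methoxy","O=C1C(C(=O)OCC)=Cc2ccc(OC)cc2O1",32.9,91,36.5,NA,1.56,1.59,"test",FALSE
29,"M4","3-cyano; 7-methoxy","O=C1C(C#N)=Cc2ccc(OC)cc2O1",35,57.5,34.8,NA,1.54,1.62,"train",FALSE
30,"N2","3-methoxycarbonyl; 6-methoxy","O=C1C(C(=O)OC)=Cc2cc(OC)ccc2O1",20.5,75.3,76,52.54,1.88,1.53,"train",FALSE
31,"N4","3-cyano; 6-methoxy","O=C1C(C#N)=Cc2cc(OC)ccc2O1",14.9,84.4,37.8,NA,1.58,1.58,"train",FALSE
32,"O1","3-acetyl; 8-ethoxy","O=C1C(C(C)=O)=Cc2cccc(OCC)c2O1",19.6,36.1,18,NA,1.26,1.55,"train",FALSE
33,"O3","3-ethoxycarbonyl; 8-ethoxy","O=C1C(C(=O)OCC)=Cc2cccc(OCC)c2O1",36,19.1,21.9,NA,1.34,1.53,"train",FALSE
34,"O4","3-cyano; 8-ethoxy","O=C1C(C#N)=Cc2cccc(OCC)c2O1",16.3,16.9,52.9,96.42,1.72,1.56,"train",FALSE
35,"O5","3-benzoyl; 8-ethoxy","O=C1C(C(=O)c3ccccc3)=Cc2cccc(OCC)c2O1",29.7,66.3,26.1,NA,1.42,1.7,"test",FALSE
36,"P2","3-methoxycarbonyl; 6-dihydroxyamino","O=C1C(C(=O)OC)=Cc2cc(N(O)O)ccc2O1",22.9,29.7,40.5,NA,1.61,1.53,"train",FALSE
37,"P3","3-ethoxycarbonyl; 6-dihydroxyamino","O=C1C(C(=O)OCC)=Cc2cc(N(O)O)ccc2O1",33.1,29.1,46.6,NA,1.67,1.61,"test",FALSE
38,"L5","3-benzoyl; 6-bromo; 8-bromo","O=C1C(C(=O)c3ccccc3)=Cc2cc(Br)cc(Br)c2O1",35.7,73,NA,NA,NA,NA,"excluded",FALSE
39,"M5","3-benzoyl; 7-methoxy","O=C1C(C(=O)c3ccccc3)=Cc2ccc(OC)cc2O1",29.3,69.2,NA,NA,NA,NA,"excluded",FALSE
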