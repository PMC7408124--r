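O=C1C(C(C)=O)=Cc2ccccc2O1 A1
O=C1C(C(=O)OC)=Cc2ccccc2O1 A2
O=C1C(C(=O)OCC)=Cc2ccccc2O1 A3
O=C1C(C#N)=Cc2ccccc2O1 A4
O=C1C(C(=O)c3ccccc3)=Cc2ccccc2O1 A5
O=C1C(C#N)=Cc2ccc(C(=O)c3ccccc3)cc2O1 C4
O=C1C(C(=O)c3ccccc3)=Cc2ccc(OCc3ccccc3)cc2O1 C5
O=C1C=Cc2ccccc2O1 COUM
O=C1C(C(C)=O)=Cc2cccc(O)c2O1 D1
O=C1C(C#N)=Cc2cccc(O)c2O1 D4
O=C1C(C(C)=O)=Cc2ccc(O)cc2O1 E1
O=C1C(C(=O)OC)=Cc2ccc(O)cc2O1 E2
O=C1C(C(=O)c3ccccc3)=Cc2ccc(O)cc2O1 E5
O=C1C(C(C)=O)=Cc2ccc(N(CC)CC)cc2O1 F1
O=C1C(C(C)=O)=Cc2cc(Br)ccc2O1 G1
O=C1C(C(=O)OC)=Cc2cc(Br)ccc2O1 G2
O=C1C(C(=O)OCC)=Cc2cc(Br)ccc2O1 G3
O=C1C(C#N)=Cc2cc(Br)ccc2O1 G4
O=C1C(C(C)=O)=Cc2cc(O)ccc2O1 J1
O=C1C(C(=O)OC)=Cc2cc(O)ccc2O1 J2
O=C1C(C(=O)OCC)=Cc2cc(O)ccc2O1 J3
O=C1C(C#N)=Cc2cc(O)ccc2O1 J4
O=C1C(C(=O)c3ccccc3)=Cc2cc(O)ccc2O1 J5
O=C1C(C(=O)OCC)=Cc2cc(Cl)ccc2O1 K3
O=C1C(C(=O)c3ccccc3)=Cc2cc(Cl)ccc2O1 K5
O=C1C(C(=O)OCC)=Cc2cc(Br)cc(Br)c2O1 L3
O=C1C(C(=O)OC)=Cc2ccc(OC)cc2O1 M2
O=C1C(C(=O)OCC)=Cc2ccc(OC)cc2O1 M3
O=C1C(C#N)=Cc2ccc(OC)cc2O1 M4
O=C1C(C(=O)OC)=Cc2cc(OC)ccc2O1 N2
O=C1C(C#N)=Cc2cc(OC)ccc2O1 N4
O=C1C(C(C)=O)=Cc2cccc(OCC)c2O1 O1
O=C1C(C(=O)OCC)=Cc2cccc(OCC)c2O1 O3
O=C1C(C#N)=Cc2cccc(OCC)c2O1 O4
O=C1C(C(=O)c3ccccc3)=Cc2cccc(OCC)c2O1 O5
O=C1C(C(=O)OC)=Cc2cc(N(O)O)ccc2O1 P2
O=C1C(C(=O)OCC)=Cc2cc(N(O)O)ccc2O1 P3
O=C1C(C(=O)c3ccccc3)=Cc2cc(Br)cc(Br)c2O1 L5
O=C1C(C(=O)c3ccccc3)=Cc2ccc(OC)cc2O1 M5
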