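# Theoretical maximum residue SASA (A^2), generated by abtap::buildMaxSasaTable()
# extended Ala-X-Ala tripeptide (phi=-120, psi=+120), probe 1.40 A, 960 points
"aa","max_sasa"
"A",110.98
"R",280.8028
"N",191.3911
"D",190.8176
"C",145.302
"Q",222.4842
"E",220.9941
"G",86.8859
"H",252.6042
"I",200.0426
"L",200.0426
"K",224.0178
"M",201.1185
"F",289.6084
"P",170.8582
"S",133.7467
"T",169.3947
"W",377.0785
"Y",312.2493
"V",170.8582
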