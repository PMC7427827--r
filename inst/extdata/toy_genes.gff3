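##gff-version 3
##sequence-region 1 1 1000000
##sequence-region 2 1 500000
1	toyanno	gene	110000	120000	.	+	.	ID=g01;description=expressed protein
1	toyanno	gene	130000	140000	.	-	.	ID=g02;description=retrotransposon protein putative
1	toyanno	gene	150000	165000	.	+	.	ID=g03;description=transposon protein putative unclassified
1	toyanno	gene	170000	185000	.	+	.	ID=g04;description=zinc finger protein
1	toyanno	gene	200000	215000	.	-	.	ID=g05;description=sugar transporter putative
1	toyanno	gene	230000	245000	.	+	.	ID=g06;description=E3 ubiquitin ligase
1	toyanno	gene	260000	275000	.	+	.	ID=g07;description=transposable element protein
1	toyanno	gene	300000	320000	.	-	.	ID=g08;description=calcium-dependent protein kinase
1	toyanno	gene	350000	360000	.	+	.	ID=g09;description=expressed protein
1	toyanno	gene	390000	399000	.	+	.	ID=g10;description=heat shock protein
1	toyanno	gene	395000	410000	.	-	.	ID=g11;description=membrane protein putative
1	toyanno	gene	610000	620000	.	+	.	ID=g12;description=expressed protein
1	toyanno	gene	640000	660000	.	+	.	ID=g13;description=retrotransposon putative centromere-specific
1	toyanno	gene	700000	710000	.	-	.	ID=g14;description=ABC transporter family protein
1	toyanno	gene	750000	760000	.	+	.	ID=g15;description=expressed protein
1	toyanno	gene	450000	460000	.	+	.	ID=g16;description=expressed protein
1	toyanno	gene	401000	405000	.	-	.	ID=g17;description=receptor-like kinase
1	toyanno	gene	820000	830000	.	+	.	ID=g18;description=wall-associated kinase
1	toyanno	gene	900000	910000	.	+	.	ID=g19;description=expressed protein
2	toyanno	gene	60000	70000	.	+	.	ID=g20;description=expressed protein
2	toyanno	gene	100000	110000	.	-	.	ID=g21;description=retrotransposon protein putative
2	toyanno	gene	140000	155000	.	+	.	ID=g22;description=stress-responsive protein
2	toyanno	gene	200000	210000	.	+	.	ID=g23;description=expressed protein
2	toyanno	gene	300000	310000	.	-	.	ID=g24;description=transposon protein putative
2	toyanno	gene	400000	410000	.	+	.	ID=g25;description=expressed protein
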