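SNP	CHR	BP	RISK_ALLELE	REPORTED_OR	PANEL	GENE
rs0000101	1	1000000	A	1.50	EUR	GENE1
rs0000102	1	1060000	G	1.20	EUR	GENE2
rs0000103	1	1120000	T	1.10	CHB	GENE3
rs0000104	1	1180000	C	1.35	EUR	GENE4
rs0000105	1	1240000	A	1.28	EUR	GENE5
rs0000106	1	1300000	G	1.15	CHB	GENE6
rs0000107	1	1360000	T	1.42	EUR	GENE7
rs0000108	1	1420000	C	1.05	EUR	GENE8
rs0000109	1	1480000	A	1.60	CHB	GENE9
rs0000110	1	1540000	G	1.22	EUR	GENE10
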