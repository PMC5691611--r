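category	strain	gene	region	position	description	allele	mutation_type	coding	il	count
combined	MG	mdtJ/tqsA	mdtJ/tqsA	-56/-237	Intergenic (-56/-237) del 120 bp	mdtJ/tqsA intergenic del120bp DEL	DEL	intergenic	B	23
combined	DH1	tqsA/mdtJ	tqsA/mdtJ	-239/-54	Intergenic (-239/-54) del 120 bp	mdtJ/tqsA intergenic del120bp DEL	DEL	intergenic	B	5
combined	MG	tqsA	mdtJ/tqsA	857-868	Coding (857-868/1035 nt) del 12 bp	tqsA del12bp DEL	DEL	coding	B	6
combined	DH1	pntA-tqsA	mdtJ/tqsA	na	del 3035 bp spanning pntA-pntB-tqsA	pntA-tqsA del3035bp DEL	DEL	coding	B	2
combined	MG	yhdP	yhdP	2440-2443	Coding (2440-2443/3801 nt) del 2 bp	yhdP del2bp 2440 DEL	DEL	coding	B	1
combined	MG	yhdP	yhdP	647	Coding (647/3801 nt) (TGGAGCC)1->2	yhdP dup7bp 647 INS	INS	coding	B	4
combined	MG	yhdP	yhdP	200-201	Coding (200-201/3801 nt) IS5 (-) +4 bp	yhdP IS5 200 MOB	MOB	coding	B	1
combined	DH1	yhdP	yhdP	3102-3110	Coding (3102-3110/3801 nt) IS element (+) +9 bp	yhdP IS 3102 MOB	MOB	coding	B	1
combined	DH1	yhdP	yhdP	2887-2890	Coding (2887-2890/3801 nt) del 4 bp	yhdP del4bp 2887 DEL	DEL	coding	B	1
MG1655	MG	rpoC	rpoC	359	P359L (CCA->CTA)	rpoC P359L SNP	SNP	coding	B	4
MG1655	MG	rpoC	rpoC	773	F773Y (TTC->TAC)	rpoC F773Y SNP	SNP	coding	B	6
MG1655	MG	rpoC	rpoC	1075	R1075S (CGT->AGT)	rpoC R1075S SNP	SNP	coding	B	1
MG1655	MG	cspC	cspC	33-41	Coding (33-41/210 nt) IS1 (-) +9 bp	cspC IS1 33 MOB	MOB	coding	B	1
MG1655	MG	cspC	cspC	37	Q37* (CAG->TAG)	cspC Q37* SNP	SNP	coding	E	1
MG1655	MG	rpsG	rpsG	460	Coding (460/540 nt) del 1 bp	rpsG del1bp 460 DEL	DEL	coding	B	1
MG1655	MG	rpsG	rpsG	157	L157* (TTA->TGA)	rpsG L157* SNP	SNP	coding	B	2
MG1655	MG	rph	pyrE/rph	667	Pseudogene (667/669 nt) +C	rph insC 667 INS	INS	pseudogene	E	2
MG1655	MG	pyrE/rph	pyrE/rph	na	del 82 bp	pyrE/rph del82bp DEL	DEL	intergenic	B	5
DH1	DH1	rho	rho	61	G61E (GGA->GAA)	rho G61E SNP	SNP	coding	B	2
DH1	DH1	rho	rho	80	Y80H (TAC->CAC)	rho Y80H SNP	SNP	coding	E	5
DH1	DH1	rho	rho	80	Y80C (TAC->TGC)	rho Y80C SNP	SNP	coding	B	2
DH1	DH1	rho	rho	406	T406P (ACC->CCC)	rho T406P SNP	SNP	coding	E	4
DH1	DH1	fhuA	fhuA	337-479	Coding (337-479/2244 nt) del 143 bp	fhuA del143bp 337 DEL	DEL	coding	E	1
DH1	DH1	fhuA	fhuA	1442	Coding (1442/2244 nt) (GTCATAACGACCGCCTAGGG)1->2	fhuA dup20bp 1442 INS	INS	coding	E	1
DH1	DH1	fhuA	fhuA	2107	Coding (2107/2244 nt) del 1 bp	fhuA del1bp 2107 DEL	DEL	coding	B	2
DH1	DH1	fhuA	fhuA	2129	Coding (2129/2244 nt) del 1 bp	fhuA del1bp 2129 DEL	DEL	coding	E	4
DH1	DH1	rcdA	rcdA	55	L55S (TTG->TCG)	rcdA L55S SNP	SNP	coding	E	1
DH1	DH1	rcdA	rcdA	338-341	Coding (338-341/537 nt) IS element (+) +4 bp	rcdA IS 338 MOB	MOB	coding	E	1
DH1	DH1	purB	purB	404	K404T (AAG->ACG)	purB K404T SNP	SNP	coding	B	2
DH1	DH1	purB	purB	21	S21N (AGC->AAC)	purB S21N SNP	SNP	coding	E	1
DH1	DH1	gadE	gadE	273-281	Coding (273-281/528 nt) IS element (-) +9 bp	gadE IS- 273 MOB	MOB	coding	E	2
DH1	DH1	gadE	gadE	273-281	Coding (273-281/528 nt) IS element (+) +9 bp	gadE IS+ 273 MOB	MOB	coding	E	1
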