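template_organism	template_gene	functional_module	locus_tag	regulons
Lactococcus lactis	ldh	LDH	llmg_1120	NHP6A,llrA
Lactococcus lactis	ldhB	LDH	llmg_0392	NHP6A,llrA
Lactococcus lactis	ldhB	LDH	llmg_0475	NHP6A,llrA
Lactococcus lactis	ldhX	LDH	llmg_1429	NHP6A,llrA
Lactococcus lactis	gadB	GAD	llmg_1179	NA
Lactococcus lactis	gadC	GAD	llmg_1178	NA
Lactococcus lactis	arcA	ADI pathway	llmg_2313	NHP6A,llrA,llrC,hllA
Lactococcus lactis	arcB	ADI pathway	llmg_2312	NHP6A,llrA,llrC,hllA
Lactococcus lactis	arcC1	ADI pathway	llmg_2310	NHP6A,llrA,llrC,hllA
Lactococcus lactis	arcC2	ADI pathway	llmg_2309	NHP6A,llrA,llrC,hllA
Lactococcus lactis	argF	ADI pathway	llmg_1754	NHP6A,llrA,llrC,hllA
Bacteria	ureABC	Urea degradation	llmg_1508	NA
Lactococcus lactis	atpE	F0/F1ATPase	llmg_1952	llrA,Regulon8
Lactococcus lactis	atpB	F0/F1ATPase	llmg_1951	llrA,Regulon8
Lactococcus lactis	atpF	F0/F1ATPase	llmg_1950	llrA,Regulon8
Lactococcus lactis	atpH	F0/F1ATPase	llmg_1949	llrA,Regulon8
Lactococcus lactis	atpA	F0/F1ATPase	llmg_1948	llrA,Regulon8
Lactococcus lactis	atpG	F0/F1ATPase	llmg_1947	llrA,Regulon8
Lactococcus lactis	atpD	F0/F1ATPase	llmg_1946	llrA,Regulon8
Lactococcus lactis	atpC	F0/F1ATPase	llmg_1945	llrA,Regulon8
Lactococcus lactis	rcfB	Acid response	llmg_2512	Regulon39
Lactococcus lactis	dnaK	Protein repair and protease	llmg_1574	llrA
Escherichia coli K12	groEL	Protein repair and protease	llmg_0411	llrA
Escherichia coli K12	groES	Protein repair and protease	llmg_0410	llrA
Lactococcus lactis	grpE	Protein repair and protease	llmg_1575	llrA
Lactococcus lactis	clpE	Protein repair and protease	llmg_0528	llrA
Lactococcus lactis	clpC	Protein repair and protease	llmg_0615	llrA
Lactococcus lactis	clpP	Protein repair and protease	llmg_0638	llrA
Bacillus subtilis	dltC	Envelope alterations	llmg_0878	NHP6A,llrA
Lactococcus lactis	recA	DNA repair	llmg_0374	Regulon39
Lactococcus lactis	uvr	DNA repair	llmg_0534	Regulon39
Lactococcus lactis	smn	DNA repair	llmg_1718	Regulon39
Lactococcus lactis	smn	DNA repair	llmg_1221	Regulon39
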