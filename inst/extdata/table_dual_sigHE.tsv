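gene_id	name	motif	distance	source	function
cg0378	NA	GGAACA-N16-CGTT	92	dual_sigHE_table	Putative phage-associated protein
cg0986	amtR	GGAAAC-N17-CGTT	397	dual_sigHE_table	Transcriptional repressor of nitrogen metabolism, TetR family
cg1121	NA	GGAACT-N16-CGTT	36	dual_sigHE_table	Permease, MFS type
cg1272	cseE	GGAACT-N16-CGTT	65	dual_sigHE_table	Anti-sigma E factor
cg1277	NA	GGAACC-N16-CGTT	32	dual_sigHE_table	Conserved putative membrane protein
cg2102	sigB	GGAACT-N16-CGTT	25	dual_sigHE_table	RNA polymerase sigma factor
cg2115	sugR	GCAACC-N16-CGTT	62	dual_sigHE_table	Transcriptional regulator, DeoR-family
cg2152	clgR	GGAACA-N16-AGTT	1	dual_sigHE_table	Transcriptional activator of Clp protease genes (P1)
cg2152	clgR	GGAACA-N16-CGTT	157	dual_sigHE_table	Transcriptional activator of Clp protease genes (P2)
cg2267	NA	GGAACT-N16-CGTT	23	dual_sigHE_table	Putative membrane protein
cg2380	NA	GGAACA-N16-CGTT	41	dual_sigHE_table	Putative membrane protein
cg2515	dnaJ2	GGAACA-N17-CGTT	93	dual_sigHE_table	Chaperone DnaJ2
cg2657	NA	GGAACT-N16-CGTT	23	dual_sigHE_table	Putative membrane protein, putative pseudogene
cg3100	dnaK	GGAACA-N16-CGTT	120	dual_sigHE_table	Chaperone DnaK
cg3309	NA	GGAACT-N16-CGTT	17	dual_sigHE_table	Putative secreted protein
cg3344	NA	GGAACA-N16-AGTT	0	dual_sigHE_table	3-hydroxypropanoate dehydrogenase, nitroreductase
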