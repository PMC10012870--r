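gene_id	name	motif	distance	source	function
cg0877	rshA	GGAAGA-N17-GTT	63	sigH_only_table	Anti-sigma factor
cg1127	mca	GGAATG-N17-GTT	207	sigH_only_table	Putative mycothiol S-conjugate amidase
cg1555	uvrD3	GGAATG-N17-GTT	56	sigH_only_table	DNA/RNA helicase, superfamily I
cg1709	mshC	GGAATA-N17-GTT	141	sigH_only_table	L-cysteine ligase, putative cysteine tRNA synthetase
cg1765	sufR	GGAATG-N18-GTT	30	sigH_only_table	Predicted transcriptional regulator
cg3299	trxB1	GGAATA-N17-GTT	33	sigH_only_table	Thioredoxin
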