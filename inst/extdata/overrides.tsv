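gene_id	class	reason
cg0986	dual_sigHE	amtR promoter proven dual experimentally despite A at position -31
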