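1	0	6000	geneA
1	6000	12000	geneB
1	12000	18000	geneC
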