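snp_id	mode	risk_allele	label	genotype_1	code_1	genotype_2	code_2	genotype_3	code_3
rs2240158	recessive	C	TT(0) vs CC+CT(1)	C/C	1	C/T	1	T/T	0
rs3983721	recessive	T	CC+CT(0) vs TT(1)	C/C	0	C/T	0	T/T	1
rs6583954	additive	T	CC(0) / CT(1) / TT(2)	C/C	0	C/T	1	T/T	2
rs2129575	recessive	T	GG+GT(0) vs TT(1)	G/G	0	G/T	0	T/T	1
rs174699	recessive	C	CT+TT(0) vs CC(1)	C/C	1	C/T	0	T/T	0
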