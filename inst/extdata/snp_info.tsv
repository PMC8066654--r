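snp_id	gene	alleles	pathway
rs2240158	GRIN3B	T > C	Cognitive function
rs3983721	GRIN3A	C > T	Cognitive function
rs6583954	CYP2C19	T > C	Methadone-metabolizing enzymes
rs2129575	TPH2	G > T	Dopamine and serotonin pathway
rs174699	COMT	C > T	Dopamine and serotonin pathway
rs9900001	NULL1	A > G	none
rs9900002	NULL2	C > T	none
rs9900003	NULL3	G > T	none
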