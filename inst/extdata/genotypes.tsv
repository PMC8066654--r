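sample_id	rs2240158	rs3983721	rs6583954	rs2129575	rs174699	rs9900001	rs9900002	rs9900003
S0001	C/C	T/T	C/T	G/G	T/T	A/G	C/C	G/G
S0002	T/T	C/T	C/T	G/T	C/T	A/G	C/C	G/G
S0003	C/T	C/T	T/T	G/G	C/C	A/G	C/T	G/G
S0004	C/T	C/T	T/T	G/T	C/T	A/G	C/T	G/G
S0005	C/T	T/T	C/T	G/G	C/C	A/A	C/C	G/G
S0006	T/T	T/T	T/T	T/T	C/T	A/G	C/C	G/G
S0007	C/T	C/C	C/C	G/G	C/T	G/G	C/C	G/G
S0008	C/T	C/T	T/T	G/G	T/T	A/G	T/T	G/G
S0009	C/T	T/T	C/C	G/T	C/T	A/G	C/T	G/T
S0010	C/T	T/T	T/T	T/T	C/C	A/A	C/T	G/G
S0011	C/C	T/T	C/C	G/T	C/T	G/G	C/C	G/T
S0012	C/T	T/T	C/T	T/T	C/T	A/A	C/C	G/G
S0013	T/T	C/C	T/T	T/T	T/T	A/A	C/C	G/G
S0014	C/T	C/C	T/T	T/T	C/C	A/G	C/C	G/G
S0015	C/C	C/T	C/T	G/G	C/C	A/A	C/T	G/G
S0016	C/T	C/T	T/T	G/T	C/T	A/A	C/C	G/G
S0017	C/T	C/C	C/C	G/T	C/T	A/G	C/C	G/T
S0018	C/T	C/T	T/T	T/T	T/T	A/G	C/C	G/G
S0019	T/T	C/C	C/C	G/G	T/T	A/G	C/C	G/G
S0020	T/T	C/T	C/T	T/T	T/T	A/A	C/C	G/G
S0021	C/C	C/C	C/T	G/T	C/C	A/G	C/C	G/G
S0022	C/C	C/T	T/T	T/T	C/C	G/G	C/T	G/G
S0023	T/T	C/C	C/T	G/T	C/C	A/G	C/C	G/G
S0024	T/T	C/C	C/T	G/T	C/T	A/G	C/C	G/G
S0025	C/T	C/C	C/C	G/G	C/T	A/G	C/C	G/G
S0026	C/T	C/T	T/T	G/T	C/C	A/G	C/C	G/G
S0027	C/T	C/C	C/T	G/G	C/T	A/A	C/T	G/G
S0028	C/T	C/C	C/T	T/T	C/T	A/G	T/T	G/T
S0029	T/T	T/T	T/T	G/T	C/T	A/A	C/T	G/G
S0030	C/T	C/T	C/T	G/T	C/T	A/A	C/C	G/G
S0031	T/T	C/T	C/T	T/T	C/T	A/A	C/C	G/G
S0032	T/T	C/T	T/T	G/T	C/T	A/A	C/C	G/G
S0033	C/T	C/T	C/T	G/G	T/T	A/G	C/C	G/G
S0034	C/T	C/C	T/T	T/T	C/C	A/G	C/C	G/G
S0035	C/T	T/T	C/T	G/T	C/T	G/G	C/C	G/T
S0036	C/C	C/C	T/T	G/T	C/T	A/A	C/T	G/G
S0037	C/T	T/T	C/T	T/T	C/C	A/G	C/C	G/T
S0038	C/T	C/C	C/C	G/G	C/C	A/A	C/C	G/G
S0039	T/T	C/T	C/T	G/T	T/T	A/A	C/C	G/T
S0040	C/T	C/T	C/C	T/T	C/C	A/G	C/T	G/G
S0041	T/T	C/C	T/T	G/T	C/T	A/G	C/T	G/T
S0042	C/T	C/T	T/T	G/G	T/T	A/A	C/T	G/G
S0043	C/T	C/C	T/T	G/T	C/C	A/G	C/C	G/T
S0044	T/T	C/T	C/T	G/T	T/T	A/A	C/C	G/G
S0045	T/T	C/C	T/T	G/G	T/T	A/G	T/T	G/G
S0046	C/C	T/T	C/T	G/T	C/T	A/G	C/T	G/T
S0047	C/T	C/T	C/T	G/T	C/T	A/G	C/T	G/G
S0048	C/C	T/T	C/T	G/G	C/T	A/A	C/T	G/T
S0049	C/T	C/T	C/C	T/T	C/T	A/A	C/C	G/T
S0050	C/C	T/T	C/T	G/T	C/C	A/A	C/C	G/G
S0051	C/C	C/T	C/C	G/T	C/C	A/G	C/C	G/G
S0052	C/T	C/C	C/C	G/G	C/T	A/A	T/T	G/G
S0053	C/T	C/C	C/T	G/G	C/T	A/G	C/C	G/G
S0054	T/T	C/C	C/C	G/G	C/T	A/A	C/C	G/G
S0055	C/T	T/T	C/T	G/T	C/T	A/G	C/C	G/G
S0056	C/T	T/T	T/T	G/T	C/T	A/G	C/C	G/G
S0057	C/C	C/C	C/T	G/G	C/T	A/A	C/T	G/T
S0058	C/C	C/T	C/T	G/G	C/T	A/G	C/C	G/G
S0059	T/T	C/T	T/T	G/T	C/T	A/A	C/C	G/G
S0060	C/T	C/C	C/C	G/T	T/T	A/A	T/T	G/G
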