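SNP	CHR	EA	OA	EAF	BETA	SE	P	N
rs13005050	2	C	T	0.14	0.0009	0.0006	0.103	439303
rs4956201	4	C	A	0.89	-0.0006	0.0008	0.442	439303
rs6816769	4	C	T	0.89	0.0004	0.0006	0.481	439303
rs78422482	4	A	G	0.01	-0.0006	0.001	0.515	439303
rs73155039	7	A	G	0.99	-0.0004	0.0019	0.835	439303
rs2976950	8	A	G	0.6	0.0018	0.0004	4.52E-07	439303
rs151226594	11	G	T	0.01	0.0012	0.0014	0.39	439303
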