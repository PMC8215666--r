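SNP	CHR	EA	OA	EAF	BETA	SE	P	N
rs13005050	2	C	T	0.14	-0.0027	0.0014	0.0629	439303
rs4956201	4	C	A	0.89	0.0001	0.002	0.961	439303
rs6816769	4	C	T	0.89	0.0006	0.0014	0.653	439303
rs78422482	4	A	G	0.01	0.0024	0.0024	0.31	439303
rs73155039	7	A	G	0.99	0.0034	0.0052	0.523	439303
rs2976950	8	A	G	0.6	0.0007	0.001	0.437	439303
rs151226594	11	G	T	0.01	0.003	0.0034	0.367	439303
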