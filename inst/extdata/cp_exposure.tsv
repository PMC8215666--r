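SNP	CHR	EA	OA	EAF	BETA	SE	P	N
rs13005050	2	C	T	0.14	0.1432	0.031	3.76E-06	34615
rs4956201	4	C	A	0.89	0.2406	0.0474	3.89E-07	34615
rs6816769	4	C	T	0.89	0.1348	0.0294	4.57E-06	34615
rs78422482	4	A	G	0.01	0.2425	0.051	2.02E-06	34615
rs73155039	7	A	G	0.99	0.8316	0.1757	2.22E-06	34615
rs2976950	8	A	G	0.6	0.0963	0.0195	7.99E-07	34615
rs151226594	11	G	T	0.01	0.3671	0.0768	1.75E-06	34615
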