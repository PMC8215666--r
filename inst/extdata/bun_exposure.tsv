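SNP	CHR	EA	OA	EAF	BETA	SE	P	N
rs10874312	1	A	G	0.66	0.007	0.0009	1.73E-14	439303
rs760077	1	A	T	0.41	0.0134	0.001	2.1E-44	439303
rs34773350	2	C	T	0.86	0.0083	0.0012	2.9E-11	439303
rs9849724	3	G	T	0.46	0.0047	0.0009	4.09E-08	439303
rs4976646	5	C	T	0.34	0.0073	0.0009	2.91E-15	439303
rs13230625	7	A	G	0.7	0.0134	0.0013	1.08E-26	439303
rs6597862	10	C	A	0.76	0.0058	0.001	8.33E-09	439303
rs3925584	11	T	C	0.55	0.0096	0.0009	9.85E-29	439303
rs4886755	15	G	A	0.51	0.0095	0.0009	1.73E-28	439303
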