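SNP	CHR	EA	OA	EAF	BETA	SE	P	N
rs11694902	2	A	G	0.76	0.005	0.0004	3.28E-34	439303
rs17462630	2	C	G	0.14	0.0041	0.0005	2.14E-16	439303
rs9868185	3	G	A	0.31	0.0055	0.0004	4.04E-37	439303
rs12920176	16	A	C	0.79	0.0026	0.0004	1.01E-09	439303
rs113445505	19	T	C	0.2	0.0096	0.0005	1.21E-99	439303
rs6127099	20	T	A	0.34	0.0034	0.0004	1.53E-20	439303
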