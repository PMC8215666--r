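SNP	CHR	EA	OA	EAF	BETA	SE	P	N
rs11694902	2	A	G	0.76	0.0047	0.0257	0.856	34615
rs17462630	2	C	G	0.14	0.0026	0.0189	0.891	34615
rs9868185	3	G	A	0.31	0.0012	0.0182	0.947	34615
rs12920176	16	A	C	0.79	0.0002	0.0186	0.992	34615
rs113445505	19	T	C	0.2	-0.0089	0.0184	0.626	34615
rs6127099	20	T	A	0.34	0.0001	0.0211	0.994	34615
rs10874312	1	A	G	0.66	0.0035	0.0187	0.851	34615
rs760077	1	A	T	0.41	-0.0124	0.0184	0.499	34615
rs34773350	2	C	T	0.86	0.0034	0.0257	0.894	34615
rs9849724	3	G	T	0.46	0.0043	0.018	0.813	34615
rs4976646	5	C	T	0.34	0.0033	0.0196	0.867	34615
rs13230625	7	A	G	0.7	0.0077	0.0262	0.771	34615
rs6597862	10	C	A	0.76	-0.0011	0.021	0.959	34615
rs3925584	11	T	C	0.55	0.0078	0.0183	0.669	34615
rs4886755	15	G	A	0.51	-0.0047	0.0175	0.789	34615
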