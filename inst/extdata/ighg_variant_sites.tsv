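# IGHG exonic variant site catalog, format v1
segment	rsid	chr14_pos	exon	imgt_num	eu_num	exonic_pos	ref	alt	aa_ref	aa_alt	allotype_switch	grantham	pooled_freq
IGHG1	rs11552998	106209340	CH1	19	140	68	G	A					0.006
IGHG1	rs17850096	106209289	CH1	40	157	119	G	C					0.001
IGHG1	rs1071803	106209119	CH1	120	214	289	A	G	K	R	Gm17>Gm3	26	0.143
IGHG1	rs587690960	106208471	CH2	22	260	89	A	G					0.003
IGHG1	rs377538050	106208364	CH2	84.3	296	196	A	T	Y	F		22	0.001
IGHG1	rs193160354	106208327	CH2	91	308	233	C	T					0.011
IGHG1	rs1043109	106208326	CH2	92	309	234	C	G	L	V		32	0.011
IGHG1	rs1043249	106208306	CH2	98	315	254	T	C					0.011
IGHG1	rs11557940	106208107	CH3	5	349	26	C	T					0.001
IGHG1	rs1045853	106208086	CH3	12	356	47	T	G	D	E	Gm1>nGm1	45	0.118
IGHG1	rs11621259	106208082	CH3	14	358	51	C	A	L	M	Gm1>nGm1	15	0.118
IGHG1	rs17841087	106207933	CH3	86	407	200	C	T					0.114
IGHG1	rs113804727	106207862	CH3	110	431	271	C	G	A	G	nGm2>Gm2	60	0.27
IGHG1	rs370028332	106207858	CH3	112	432	275	G	C					0.001
IGHG1	rs8011686	106207843	CH3	117	437	290	G	A					0.003
IGHG1	rs12879979	106207822	CH3	124	444	311	T	C					0.106
IGHG2	rs189328740	106111071	CH1	15	136	56	C	T					0.023
IGHG2	rs587648672	106111069	CH1	16	137	58	A	G	E	G		98	0.023
IGHG2	rs773818177	106111067	CH1	17	138	60	A	G	S	G		56	0.023
IGHG2	rs11557955	106110966	CH1	82	171	161	A	G					0.157
IGHG2	rs11627594	106110914	CH1	92	189	213	C	A	P	T		38	0.105
IGHG2	rs8009156	106110137	CH2	45.1	282	150	G	A	V	M	Gm(.)>Gm23	21	0.103
IGHG2	rs11160859	106110057	CH2	91	308	230	T	C					0.163
IGHG2	rs113678609	106110056	CH2	92	309	231	G	C	V	L		32	0.003
IGHG2	rs587682450	106109825	CH3	9	353	38	A	C					0.017
IGHG2	rs4983499	106109752	CH3	38	378	111	G	T	A	S		99	0.003
IGHG2	rs368359789	106109708	CH3	79	392	155	G	C	K	N		94	0.001
IGHG2	rs1049810	106109702	CH3	81	394	161	A	G					0.054
IGHG2	rs28371022	106109573	CH3	117	437	290	G	A					0.106
IGHG3	rs2983777	106237642	CH1	30	151	101	C	A					0.001
IGHG3	rs12050095	106237624	CH1	40	157	119	G	A					0.025
IGHG3	rs138869693	106236202	CH2	35	271	122	C	T					0.006
IGHG3	rs145035200	106236195	CH2	38	274	129	C	A	Q	K		53	0.006
IGHG3	rs74093865	106236143	CH2	82	291	181	C	T	P	L	nGm21>Gm21	98	0.797
IGHG3	rs60746425	106236141	CH2	83	292	183	C	T	R	W	nGm16>Gm16	101	0.048
IGHG3	rs12890621	106236128	CH2	84.3	296	196	A	T	Y	F		22	0.123
IGHG3	rs201027762	106236035	CH2	110	327	289	C	G	A	G		60	0.006
IGHG3	rs141959627	106236000	CH2	124	339	324	A	G	T	A		58	0.006
IGHG3	rs189025987	106235895	CH3	1.4	341	2	A	G					0.001
IGHG3	rs147594653	106235874	CH3	4	348	23	G	A					0.001
IGHG3	rs155533833	106235856	CH3	10	354	41	C	T					0.001
IGHG3	rs113169458	106235783	CH3	39	379	114	G	A	V	M	nGm15>Gm15	21	0.047
IGHG3	rs77307099	106235767	CH3	44	384	130	G	A	S	N	Gm11>nGm11	46	0.799
IGHG3	rs78376194	106235766	CH3	44	384	131	C	T			Gm11>nGm11		0.799
IGHG3	rs587739524	106235758	CH3	45.2	387	139	C	G	P	R		103	0.003
IGHG3	rs149653267	106235742	CH3	79	392	155	C	G	N	K		94	0.052
IGHG3	rs139413052	106235729	CH3	84	397	168	A	G	M	V		21	0.048
IGHG3	rs4042056	106235614	CH3	115	435	283	G	A	R	H	Gm5>nGm5	29	0.085
IGHG3	rs1051112	106235611	CH3	116	436	286	T	A	F	Y	Gm5>nGm5	22	0.847
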