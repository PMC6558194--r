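# Allele-table site columns (consensus coordinates), format v1
segment	exon	exonic_pos	imgt_num	eu_num	consensus	aa_annotation
IGHG1	CH1	68	19	140	G	A
IGHG1	CH1	119	40	157	G	S
IGHG1	CH1	289	120	214	A	K>R
IGHG1	CH2	89	22	260	A	T
IGHG1	CH2	196	84.3	296	A	Y>F
IGHG1	CH2	212	85.1	301	C	R
IGHG1	CH2	233	91	308	C	V
IGHG1	CH2	234	92	309	C	L>V
IGHG1	CH2	254	98	315	T	N
IGHG1	CH3	26	5	349	C	Y
IGHG1	CH3	47	12	356	T	D>E
IGHG1	CH3	51	14	358	C	L>M
IGHG1	CH3	200	86	407	C	Y
IGHG1	CH3	243	101	422	G	C>I
IGHG1	CH3	271	110	431	C	A>G
IGHG1	CH3	275	112	432	G	L
IGHG1	CH3	290	117	437	G	T
IGHG1	CH3	311	124	444	T	S
IGHG2	CH1	56	15	136	C	S
IGHG2	CH1	58	16	137	A	E>G
IGHG2	CH1	60	17	138	A	S>G
IGHG2	CH1	68	19	140	C	A
IGHG2	CH1	161	82	171	A	P
IGHG2	CH1	213	92	189	C	P>T
IGHG2	CH1	223	95	192	A	N>S
IGHG2	CH1	227	96	193	C	F>L
IGHG2	CH2	150	45.1	282	G	V>M
IGHG2	CH2	230	91	308	T	V
IGHG2	CH2	231	92	309	G	V>L
IGHG2	CH3	38	9	353	A	P
IGHG2	CH3	111	38	378	G	A>S
IGHG2	CH3	155	79	392	G	K>N
IGHG2	CH3	161	81	394	A	T
IGHG2	CH3	290	117	437	G	T
IGHG3	CH1	2	1.4	118	T	S
IGHG3	CH1	101	30	151	C	S
IGHG3	CH1	119	40	157	G	S
IGHG3	CH1	175	84.3	176	C	S>Y
IGHG3	CH1	223	95	192	G	S>N
IGHG3	CH1	227	96	193	G	L>F
IGHG3	H1	29	10		A	
IGHG3	H2	29	10		G	
IGHG3	H3	36	13		A	
IGHG3	H4	10			G	
IGHG3	H4	13			T	
IGHG3	CH2	122	35	271	C	P
IGHG3	CH2	129	38	274	C	Q>K
IGHG3	CH2	181	82	291	C	P>L
IGHG3	CH2	183	83	292	C	R>W
IGHG3	CH2	196	84.3	296	A	Y>F
IGHG3	CH2	234	92	309	C	L>V
IGHG3	CH2	289	110	327	C	A>G
IGHG3	CH2	324	124	339	A	T>A
IGHG3	CH3	2	1.4	341	A	S
IGHG3	CH3	23	4	348	G	V
IGHG3	CH3	41	10	354	C	S
IGHG3	CH3	114	39	379	G	V>M
IGHG3	CH3	130	44	384	G	S>N
IGHG3	CH3	131	44	384	C	S>N
IGHG3	CH3	139	45.2	387	C	P>R
IGHG3	CH3	155	79	392	C	N>K
IGHG3	CH3	161	81	394	G	SIN
IGHG3	CH3	168	84	397	A	M>V
IGHG3	CH3	205	88	409	A	K>R
IGHG3	CH3	209	89	410	C	SIN
IGHG3	CH3	212	90	411	C	SIN
IGHG3	CH3	234	98	419	C	Q>E
IGHG3	CH3	242	100	421	C	SIN
IGHG3	CH3	243	101	422	A	I>V
IGHG3	CH3	283	115	435	G	R>H
IGHG3	CH3	286	116	436	T	F>Y
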