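# IGHG allele catalog (copies = chromosomes observed), format v1
segment	name	status	genbank	allotypes	hinge_absent	variant_states	copies
IGHG1	IGHG1*01	baseline		17,1			0
IGHG1	IGHG1*02	baseline		17,1		CH2:212:T	391
IGHG1	IGHG1*03	baseline		3		CH1:289:G;CH2:212:T;CH3:47:G;CH3:51:A;CH3:200:T;CH3:311:C	81
IGHG1	IGHG1*04	baseline		17,1,27		CH2:212:T;CH3:243:A	0
IGHG1	IGHG1*05	baseline		17,1		CH1:68:A;CH2:212:T;CH3:290:A	2
IGHG1	IGHG1*06	novel	MG920252	3		CH1:289:G;CH2:212:T;CH3:47:G;CH3:51:A;CH3:200:T;CH3:275:C;CH3:311:C	1
IGHG1	IGHG1*07	novel	MG920245	17,1,2		CH2:212:T;CH3:271:G	189
IGHG1	IGHG1*08	novel	MG920246	3,1		CH1:289:G;CH2:212:T	18
IGHG1	IGHG1*09	novel	MG920247	17,1		CH1:68:A;CH2:212:T	2
IGHG1	IGHG1*10	novel	MG920248	17,1		CH2:89:G;CH2:212:T	2
IGHG1	IGHG1*11	novel	MG920249	17,1		CH2:212:T;CH2:233:T;CH2:234:G;CH2:254:C	7
IGHG1	IGHG1*12	novel	MG920250	17,1		CH2:212:T;CH3:26:T	1
IGHG1	IGHG1*13	novel	MG920251	17,1		CH2:196:T;CH2:212:T	1
IGHG1	IGHG1*14	novel	MG920253	17,1		CH1:119:C;CH2:212:T	1
IGHG2	IGHG2*01	baseline		(..)			0
IGHG2	IGHG2*02	baseline		23		CH1:68:G;CH1:161:G;CH1:213:A;CH2:150:A;CH2:230:C;CH3:290:A	71
IGHG2	IGHG2*03	baseline		(..)		CH1:68:G	557
IGHG2	IGHG2*04	baseline		(..)		CH1:68:G;CH1:223:G;CH1:227:G	0
IGHG2	IGHG2*05	baseline		(..)		CH1:68:G;CH3:161:G	0
IGHG2	IGHG2*06	baseline		(..)		CH1:68:G;CH1:161:G;CH2:230:C;CH3:111:T;CH3:290:A	2
IGHG2	IGHG2*07	novel	MH025828	(..)		CH1:68:G;CH2:230:C	4
IGHG2	IGHG2*08	novel	MH025829	(..)		CH1:68:G;CH1:161:G;CH2:230:C;CH3:161:G	30
IGHG2	IGHG2*09	novel	MH025830	(..)		CH1:56:T;CH1:58:G;CH1:60:G;CH1:68:G	16
IGHG2	IGHG2*10	novel	MH025831	(..)		CH1:68:G;CH3:38:C	12
IGHG2	IGHG2*11	novel	MH025832	(..)		CH1:68:G;CH1:161:G;CH2:230:C;CH2:231:C;CH3:161:G	1
IGHG2	IGHG2*12	novel	MH025833	(..)		CH1:68:G;CH1:161:G	3
IGHG2	IGHG2*13	novel	MH025834	(..)		CH1:68:G;CH2:230:C;CH3:161:G	8
IGHG2	IGHG2*14	novel	MH025835	(..)		CH1:68:G;CH1:161:G;CH2:230:C;CH2:231:C	1
IGHG2	IGHG2*15	novel	MH025836	(..)		CH1:68:G;CH1:161:G;CH2:230:C;CH3:155:C;CH3:161:G	1
IGHG3	IGHG3*01	baseline		5,10,11,13,14,26,27			2
IGHG3	IGHG3*03	baseline		5,6,11,24,26	H2	CH3:168:G;CH3:205:G;CH3:209:A;CH3:234:G;CH3:242:T;CH3:243:G	0
IGHG3	IGHG3*04	baseline		5,10,11,13,14,26,27	H2;H3	CH1:2:C	0
IGHG3	IGHG3*05	baseline		5,10,11,13,14,26,27			0
IGHG3	IGHG3*06	baseline		5,10,11,13,14,26,27		CH1:101:A;CH3:2:G;CH3:155:G	0
IGHG3	IGHG3*07	baseline		5,10,11,13,14,26,27		CH3:2:G;CH3:155:G	0
IGHG3	IGHG3*08	baseline		5,14,26,27		CH3:130:A;CH3:131:T	0
IGHG3	IGHG3*09	baseline		5,10,11,13,14,26,27		CH2:234:G;CH3:212:T	0
IGHG3	IGHG3*10	baseline		5,10,11,13,14,26,27		CH1:101:A	1
IGHG3	IGHG3*11	baseline		5,10,11,13,14,26,27		H4:10:A;H4:13:C;CH2:196:T	76
IGHG3	IGHG3*12	baseline		5,10,11,13,14,26,27	H3	H4:10:A;H4:13:C;CH2:196:T	7
IGHG3	IGHG3*13	baseline		5,6,10,11,14,26,27		CH3:155:G;CH3:161:A;CH3:234:G	0
IGHG3	IGHG3*14	baseline		21,26,27,28		CH2:181:T;CH3:130:A;CH3:131:T;CH3:286:A	529
IGHG3	IGHG3*15	baseline		21,26,27,28		CH2:181:T;CH3:130:A;CH3:131:T;CH3:155:G;CH3:286:A	1
IGHG3	IGHG3*16	baseline		21,26,27,28		CH2:181:T;CH2:324:G;CH3:130:A;CH3:131:T;CH3:286:A	5
IGHG3	IGHG3*17	baseline		10,11,13,15,27	H2	CH1:223:A;CH1:227:C;H3:36:G;CH3:114:A;CH3:155:G;CH3:168:G;CH3:283:A;CH3:286:A	0
IGHG3	IGHG3*18	baseline		10,11,13,15,16,27	H2	CH1:175:A;H3:36:G;CH2:183:T;CH3:114:A;CH3:155:G;CH3:168:G;CH3:283:A;CH3:286:A	0
IGHG3	IGHG3*19	baseline		10,11,13,15,16,27	H2	H3:36:G;CH2:183:T;CH3:114:A;CH3:155:G;CH3:168:G;CH3:283:A;CH3:286:A	31
IGHG3	IGHG3*20	novel	MG920256	21,26,27,28		CH2:181:T;CH3:130:A;CH3:131:T;CH3:139:G;CH3:286:A	2
IGHG3	IGHG3*21	novel	MG920255	5,10,11,13,14,26,27		CH1:119:A	18
IGHG3	IGHG3*22	novel	MG920254	21,27		CH2:181:T;CH3:130:A;CH3:131:T;CH3:283:A;CH3:286:A	26
IGHG3	IGHG3*23	novel	MH025837	10,11,13,16,27	H2	H3:36:G;CH2:183:T;CH3:155:G;CH3:168:G;CH3:283:A;CH3:286:A	1
IGHG3	IGHG3*24	novel	MG920257	26,27,28		CH3:130:A;CH3:131:T;CH3:155:G;CH3:286:A	2
IGHG3	IGHG3*25	novel	MG920258	21,26,27,28		CH2:122:T;CH2:129:A;CH2:181:T;CH3:130:A;CH3:131:T;CH3:286:A	4
IGHG3	IGHG3*26	novel	MG920259	5,10,11,13,14,26,27		CH2:196:T;CH2:289:G	4
IGHG3	IGHG3*27	novel	MG920260	26,27,28		CH2:181:T;CH3:23:A;CH3:130:A;CH3:131:T;CH3:286:A	1
IGHG3	IGHG3*28	novel	MG786813	5,10,11,13,14,26,27		H4:10:A;H4:13:C;CH2:196:T;CH3:41:T	1
IGHG3	IGHG3*29	novel	MG920261	21,26,27,28		CH2:181:T;CH3:2:G;CH3:130:A;CH3:131:T;CH3:286:A	1
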