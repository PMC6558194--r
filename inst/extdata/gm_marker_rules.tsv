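# Gm marker state rules (conjunctive over sites), format v1
marker_class	marker	segment	required_states	display_order
G1m	17	IGHG1	CH1:289:A	1
G1m	3	IGHG1	CH1:289:G	2
G1m	1	IGHG1	CH3:47:T;CH3:51:C	3
G1m	2	IGHG1	CH3:271:G	4
G1m	27	IGHG1	CH3:243:A	5
G2m	23	IGHG2	CH2:150:A	1
G3m	5	IGHG3	CH3:283:G;CH3:286:T	1
G3m	6	IGHG3	CH3:234:G	2
G3m	10	IGHG3	CH3:130:G;CH3:131:C;CH3:205:A	3
G3m	11	IGHG3	CH3:130:G;CH3:131:C	4
G3m	13	IGHG3	CH3:130:G;CH3:131:C;CH3:234:C	5
G3m	14	IGHG3	CH3:168:A;CH3:286:T	6
G3m	15	IGHG3	CH3:114:A	7
G3m	16	IGHG3	CH2:183:T	8
G3m	21	IGHG3	CH2:181:T	9
G3m	24	IGHG3	CH3:243:G	10
G3m	26	IGHG3	CH3:283:G	11
G3m	27	IGHG3	CH3:205:A	12
G3m	28	IGHG3	CH3:130:A;CH3:283:G;CH3:286:A	13
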