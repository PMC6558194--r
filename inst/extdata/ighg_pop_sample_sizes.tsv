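# Per-population per-segment sample sizes and printed HWE p-values, format v1
segment	population	n_individuals	hw_p
IGHG1	GKW	46	1
IGHG1	GND	48	0.086
IGHG1	GRC	51	0.912
IGHG1	KIV	50	0.836
IGHG1	KRC	52	0.889
IGHG1	BrJAP	55	0.530
IGHG1	CTBA	56	0.530
IGHG2	GKW	46	1
IGHG2	GND	48	1
IGHG2	GRC	51	1
IGHG2	KIV	52	1
IGHG2	KRC	52	1
IGHG2	BrJAP	57	0.232
IGHG2	CTBA	47	0.146
IGHG3	GKW	46	
IGHG3	GND	48	1
IGHG3	GRC	51	1
IGHG3	KIV	52	1
IGHG3	KRC	51	1
IGHG3	BrJAP	57	0.951
IGHG3	CTBA	51	0.519
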