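# Per-population IGHG allele frequencies (printed values verbatim), format v1
segment	allele	population	frequency
IGHG1	IGHG1*02	GKW	0.522
IGHG1	IGHG1*02	GND	0.438
IGHG1	IGHG1*02	GRC	0.725
IGHG1	IGHG1*02	KIV	0.77
IGHG1	IGHG1*02	KRC	0.606
IGHG1	IGHG1*02	BrJAP	0.6
IGHG1	IGHG1*02	CTBA	0.228
IGHG1	IGHG1*03	GND	0.094
IGHG1	IGHG1*03	GRC	0.02
IGHG1	IGHG1*03	KIV	0.02
IGHG1	IGHG1*03	KRC	0.029
IGHG1	IGHG1*03	CTBA	0.707
IGHG1	IGHG1*05	CTBA	0.022
IGHG1	IGHG1*06	CTBA	0.011
IGHG1	IGHG1*07	GKW	0.478
IGHG1	IGHG1*07	GND	0.469
IGHG1	IGHG1*07	GRC	0.235
IGHG1	IGHG1*07	KIV	0.2
IGHG1	IGHG1*07	KRC	0.365
IGHG1	IGHG1*07	BrJAP	0.136
IGHG1	IGHG1*07	CTBA	0.033
IGHG1	IGHG1*08	KIV	0.01
IGHG1	IGHG1*08	BrJAP	0.155
IGHG1	IGHG1*09	BrJAP	0.018
IGHG1	IGHG1*10	BrJAP	0.018
IGHG1	IGHG1*11	BrJAP	0.064
IGHG1	IGHG1*12	GRC	0.01
IGHG1	IGHG1*13	BrJAP	0.009
IGHG1	IGHG1*14	GRC	0.01
IGHG2	IGHG2*02	GND	0.083
IGHG2	IGHG2*02	GRC	0.02
IGHG2	IGHG2*02	KIV	0.038
IGHG2	IGHG2*02	KRC	0.029
IGHG2	IGHG2*02	BrJAP	0.114
IGHG2	IGHG2*02	CTBA	0.436
IGHG2	IGHG2*03	GKW	0.957
IGHG2	IGHG2*03	GND	0.885
IGHG2	IGHG2*03	GRC	0.735
IGHG2	IGHG2*03	KIV	0.942
IGHG2	IGHG2*03	KRC	0.952
IGHG2	IGHG2*03	BrJAP	0.579
IGHG2	IGHG2*03	CTBA	0.489
IGHG2	IGHG2*06	CTBA	0.021
IGHG2	IGHG2*07	GKW	0.033
IGHG2	IGHG2*07	KRC	0.01
IGHG2	IGHG2*08	GRC	0.01
IGHG2	IGHG2*08	KIV	0.019
IGHG2	IGHG2*08	KRC	0.01
IGHG2	IGHG2*08	BrJAP	0.202
IGHG2	IGHG2*08	CTBA	0.032
IGHG2	IGHG2*09	GKW	0.011
IGHG2	IGHG2*09	GND	0.01
IGHG2	IGHG2*09	GRC	0.137
IGHG2	IGHG2*10	GND	0.021
IGHG2	IGHG2*10	GRC	0.098
IGHG2	IGHG2*11	BrJAP	0.009
IGHG2	IGHG2*12	BrJAP	0.018
IGHG2	IGHG2*12	CTBA	0.011
IGHG2	IGHG2*13	BrJAP	0.061
IGHG2	IGHG2*13	CTBA	0.011
IGHG2	IGHG2*14	BrJAP	0.009
IGHG2	IGHG2*15	BrJAP	0.009
IGHG3	IGHG3*01	CTBA	0.02
IGHG3	IGHG3*10	CTBA	0.01
IGHG3	IGHG3*11	GND	0.094
IGHG3	IGHG3*11	GRC	0.01
IGHG3	IGHG3*11	KIV	0.038
IGHG3	IGHG3*11	KRC	0.02
IGHG3	IGHG3*11	CTBA	0.588
IGHG3	IGHG3*12	CTBA	0.069
IGHG3	IGHG3*14	GKW	1.0
IGHG3	IGHG3*14	GND	0.844
IGHG3	IGHG3*14	GRC	0.833
IGHG3	IGHG3*14	KIV	0.952
IGHG3	IGHG3*14	KRC	0.971
IGHG3	IGHG3*14	BrJAP	0.474
IGHG3	IGHG3*14	CTBA	0.186
IGHG3	IGHG3*15	BrJAP	0.009
IGHG3	IGHG3*16	KIV	0.01
IGHG3	IGHG3*16	CTBA	0.039
IGHG3	IGHG3*19	BrJAP	0.272
IGHG3	IGHG3*20	BrJAP	0.018
IGHG3	IGHG3*21	BrJAP	0.158
IGHG3	IGHG3*22	GND	0.063
IGHG3	IGHG3*22	GRC	0.157
IGHG3	IGHG3*22	KRC	0.01
IGHG3	IGHG3*22	CTBA	0.029
IGHG3	IGHG3*23	BrJAP	0.009
IGHG3	IGHG3*24	BrJAP	0.018
IGHG3	IGHG3*25	BrJAP	0.035
IGHG3	IGHG3*26	CTBA	0.039
IGHG3	IGHG3*27	CTBA	0.01
IGHG3	IGHG3*28	CTBA	0.01
IGHG3	IGHG3*29	BrJAP	0.009
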