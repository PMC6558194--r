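# Gm allotype haplotype frequencies inferred from sequencing (printed), format v1
lefranc_id	gm_string	population	frequency
A	5,10,11,13,14,26,27;3;23	GND	0.083
A	5,10,11,13,14,26,27;3;23	GRC	0.01
A	5,10,11,13,14,26,27;3;23	KIV	0.02
A	5,10,11,13,14,26,27;3;23	KRC	0.02
A	5,10,11,13,14,26,27;3;23	CTBA	0.444
B	5,10,11,13,14,26,27;3;(.)	GND	0.01
B	5,10,11,13,14,26,27;3;(.)	CTBA	0.277
C	21,26,27,28;17,1;(.)	GKW	0.522
C	21,26,27,28;17,1;(.)	GND	0.375
C	21,26,27,28;17,1;(.)	GRC	0.588
C	21,26,27,28;17,1;(.)	KIV	0.77
C	21,26,27,28;17,1;(.)	KRC	0.608
C	21,26,27,28;17,1;(.)	BrJAP	0.384
C	21,26,27,28;17,1;(.)	CTBA	0.211
D	21,26,27,28;17,1,2;(.)	GKW	0.478
D	21,26,27,28;17,1,2;(.)	GND	0.468
D	21,26,27,28;17,1,2;(.)	GRC	0.235
D	21,26,27,28;17,1,2;(.)	KIV	0.2
D	21,26,27,28;17,1,2;(.)	KRC	0.363
D	21,26,27,28;17,1,2;(.)	BrJAP	0.134
D	21,26,27,28;17,1,2;(.)	CTBA	0.011
I	10,11,13,15,16,27;17,1;(.)	BrJAP	0.286
J	5,10,11,13,14,26,27;3,1;23	KIV	0.01
J	5,10,11,13,14,26,27;3,1;23	BrJAP	0.107
K	5,10,11,13,14,26,27;3,1;(.)	BrJAP	0.045
	21,26,27,28;3;23	GRC	0.01
	5,10,11,13,14,26,27;17,1;23	BrJAP	0.009
	10,11,13,16,27;17,1;(.)	BrJAP	0.009
	21,27;17,1,2;(.)	CTBA	0.022
	21,27;17,1;(.)	GND	0.063
	21,27;17,1;(.)	GRC	0.157
	21,27;17,1;(.)	KRC	0.01
	21,27;17,1;(.)	CTBA	0.011
	5,10,11,13,14,26,27;17,1;(.)	CTBA	0.022
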