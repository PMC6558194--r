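# Pairwise FST (printed estimates and significance codes), format v1
pop1	pop2	fst	significance
GND	GKW	0.02828	**
GRC	GKW	0.10738	***
GRC	GND	0.0772	***
KIV	GKW	0.10494	***
KIV	GND	0.1112	***
KIV	GRC	0.05722	***
KRC	GKW	0.01042	ns
KRC	GND	0.03816	**
KRC	GRC	0.06889	***
KRC	KIV	0.0322	ns
BrJAP	GKW	0.21496	***
BrJAP	GND	0.15144	***
BrJAP	GRC	0.11437	***
BrJAP	KIV	0.18492	***
BrJAP	KRC	0.19168	***
CTBA	GKW	0.51577	***
CTBA	GND	0.38142	***
CTBA	GRC	0.41023	***
CTBA	KIV	0.5127	***
CTBA	KRC	0.50134	***
CTBA	BrJAP	0.28576	***
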