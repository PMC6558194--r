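# Sample sizes for the Gm haplotype frequency table, format v1
population	n_individuals
GKW	46
GND	48
GRC	51
KIV	50
KRC	51
BrJAP	55
CTBA	44
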