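# Lefranc letter identifiers for Gm allotype haplotype strings, format v1
lefranc_id	gm_string
A	5,10,11,13,14,26,27;3;23
B	5,10,11,13,14,26,27;3;(.)
C	21,26,27,28;17,1;(.)
D	21,26,27,28;17,1,2;(.)
I	10,11,13,15,16,27;17,1;(.)
J	5,10,11,13,14,26,27;3,1;23
K	5,10,11,13,14,26,27;3,1;(.)
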