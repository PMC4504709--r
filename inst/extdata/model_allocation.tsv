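orientation	n_shift	scope
A	-5	truncated
A	0	full
A	3	truncated
A	5	truncated
A	10	full
B	-5	truncated
B	0	full
B	3	truncated
B	5	truncated
B	10	full
C	-5	truncated
C	0	full
C	3	truncated
C	5	truncated
C	10	full
D	-5	truncated
D	0	full
D	3	truncated
D	5	truncated
D	10	full
E	-5	truncated
E	0	full
E	3	truncated
E	5	truncated
E	10	full
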