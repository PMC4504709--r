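class	cutoff	precedence
acid-base	4.0	1
hydrogen-bond	3.5	2
aromatic	7.0	3
hydrophobic	5.4	4
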