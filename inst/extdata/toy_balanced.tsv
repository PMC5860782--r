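# protein_a	interface_a	protein_b	interface_b
A	i1	B	i1
B	i1	C	i1
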