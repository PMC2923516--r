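strain_id	mating_type	lineage	pair_id
L1A	A	1	L1
L1a	a	1	L1
L2A	A	2	L2
L2a	a	2	L2
L3A	A	3	L3
L3a	a	3	L3
L4A	A	4	L4
L4a	a	4	L4
L5A	A	5	L5
L5a	a	5	L5
L6A	A	6	L6
L6a	a	6	L6
L7A	A	7	L7
L7a	a	7	L7
L8(1)A	A	8	L8(1)
L8(1)a	a	8	L8(1)
L8(2)A	A	8	L8(2)
L8(2)a	a	8	L8(2)
L9A	A	9	L9
L9a	a	9	L9
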