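event_id	gene	pairs	lineages	template	ancestral
1	cys-5	L5,L6	5,6	mat_a	TRUE
2	ser-3	L3,L8(1),L8(2)	3,8	mat_a	TRUE
3	ser-3	L2	2	mat_A	FALSE
4	ser-3	L4	4	mat_a	FALSE
5	ser-3	L7	7	mat_A	FALSE
6	arg-1	L3	3	mat_A	FALSE
7	lys-4	L4	4	mat_a	FALSE
8	ad-9	L8(1),L8(2)	8	mat_a	TRUE
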