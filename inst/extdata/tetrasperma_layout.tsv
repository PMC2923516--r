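gene	region_hint	coding_bp	intron_bp	mat_locus_follows	centromere_follows
ro-10	left_flank	588	300	FALSE	FALSE
nit-2	left_flank	3291	300	FALSE	FALSE
krev-1	left_flank	519	300	FALSE	FALSE
sod-1	left_flank	465	300	FALSE	FALSE
mus-42	central	1680	0	FALSE	FALSE
rid	central	2559	0	FALSE	FALSE
leu-4	central	1863	300	FALSE	FALSE
cys-5	central	882	0	FALSE	FALSE
ser-3	central	921	0	FALSE	FALSE
tef-1	central	474	300	FALSE	FALSE
un-3	central	1923	0	TRUE	FALSE
upr-1	central	2886	0	FALSE	FALSE
erg-8	central	1428	300	FALSE	FALSE
arg-1	central	1119	300	FALSE	FALSE
eth-1	central	864	300	FALSE	TRUE
lys-4	central	1053	300	FALSE	FALSE
cys-9	central	906	300	FALSE	FALSE
ad-9	central	609	300	FALSE	FALSE
al-1	central	1635	300	FALSE	FALSE
lys-3	central	3324	300	FALSE	FALSE
os-1	right_flank	1749	300	FALSE	FALSE
prd-4	right_flank	1473	300	FALSE	FALSE
arg-13	right_flank	999	300	FALSE	FALSE
phr	right_flank	1767	300	FALSE	FALSE
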