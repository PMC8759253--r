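transcript_id	cleavage_pos	mirna_id	allen_score	origin	category
PARA1	212	mir_a	0	mirna	1
PARA2	342	mir_a	0	mirna	1
PARA3	162	mir_a	0	mirna	1
TASL1	112	mir_b	1	mirna	1
ARFL1	312	TASL1_r0_D4(+)	0	secondary	1
TASL1	351	TASL1_r0_D4(+)	0	secondary	1
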