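donor_plasmid	recipient_strain	D	R	T	immune
pG0400	Dcrispr	4800000000	1300000000	80000	FALSE
pG0400	Dcrispr	4100000000	1100000000	19000	FALSE
pG0400	RP62a	13000000000	1500000000	14	TRUE
pG0400	RP62a	16000000000	1000000000	23	TRUE
pG0400mut	Dcrispr	8000000000	1300000000	150000	FALSE
pG0400mut	Dcrispr	11000000000	1700000000	50000	FALSE
pG0400mut	RP62a	16000000000	2000000000	24000	FALSE
pG0400mut	RP62a	8000000000	1400000000	40000	FALSE
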