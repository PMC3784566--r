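replicate	design	transconjugants	recipients
1	aliquots	147	208000000
2	aliquots	122	185000000
3	aliquots	129	168000000
4	aliquots	187	184000000
5	aliquots	124	180000000
6	aliquots	127	190000000
7	aliquots	158	167000000
8	aliquots	131	184000000
9	aliquots	116	158000000
10	aliquots	93	161000000
1	independent_cultures	167	202000000
2	independent_cultures	193	187000000
3	independent_cultures	80	156000000
4	independent_cultures	107	213000000
5	independent_cultures	207	149000000
6	independent_cultures	213	163000000
7	independent_cultures	907	171000000
8	independent_cultures	380	201000000
9	independent_cultures	127	175000000
10	independent_cultures	80	188000000
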