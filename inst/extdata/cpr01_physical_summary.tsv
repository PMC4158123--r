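group	length_cM	n_markers	n_unplaced	n_nonsyntenic	n_placed
LG1	75.5	170	4	0	164
LG2	71.4	117	19	8	90
LG3	75.1	132	37	8	82
LG4	86.0	429	77	10	339
LG5	87.8	55	15	2	38
LG6	99.5	156	26	4	126
LG7	80.2	220	25	1	194
LG8	77.4	57	12	3	40
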