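group	length_cM	span_Mb	n_markers
LG1	75.5	46.9	170
LG2	71.4	34.3	117
LG3	75.1	39.1	132
LG4	86.0	47.5	429
LG5	87.8	35.3	55
LG6	99.5	56.5	156
LG7	80.2	46.3	220
LG8	77.4	16.1	57
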