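locus	breed	n_ins_ins	n_ins_del	n_del_del
LEPROT-SINE-RIP	Large White	63	297	90
LEPROT-SINE-RIP	Duroc	3	16	5
LEPROT-SINE-RIP	Landrace	0	9	15
LEPROT-SINE-RIP	Sujiang	7	9	8
LEPROT-SINE-RIP	Jiangquhai	15	5	4
LEPROT-SINE-RIP	Jinhua	18	0	6
LEPROT-SINE-RIP	Rongchang	7	17	0
LEPR-SINE-RIP1	Large White	21	144	264
LEPR-SINE-RIP1	Duroc	0	11	13
LEPR-SINE-RIP1	Sujiang	0	15	9
LEPR-SINE-RIP1	Jiangquhai	0	3	15
LEPR-SINE-RIP1	Jinhua	1	7	16
LEPR-SINE-RIP2	Large White	0	269	160
LEPR-SINE-RIP2	Duroc	0	18	6
LEPR-SINE-RIP2	Landrace	0	23	1
LEPR-SINE-RIP2	Sujiang	0	16	8
LEPR-SINE-RIP2	Bama	0	21	3
LEPR-SINE-RIP2	Jiangquhai	0	8	16
LEPR-SINE-RIP2	Erhualian	0	2	22
LEPR-SINE-RIP2	Jinhua	0	9	15
LEPR-SINE-RIP2	Wuzhishan	6	14	4
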