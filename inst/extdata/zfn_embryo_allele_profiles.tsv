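sample	material	time	variant1	pct1	variant2	pct2	pct_wt
Z14	RNA	8h	24 bp DEL-A	71	8 bp DEL-B	29	0
Z15	RNA	8h	4 bp DEL-A	83		NA	16
Z16	RNA	8h	4 bp DEL-B	54		NA	39
Z17	RNA	8h	1 bp INS-A	100		NA	0
Z18	DNA	8h	A-T TV-A	3		NA	94
Z19	DNA	8h	11 bp DEL-A	12		NA	84
Z20	DNA	8h	13 single point mutation variants-A	NA		NA	79
Z22	DNA	18h	9 bp DEL-B	93	T-A TV, 9 bp DEL-B	7	0
Z24	DNA	18h	A-G TS-A	2		NA	84
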