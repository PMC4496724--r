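nucleic_acid	protein	odn	time	metric	k	n	printed_pct
DNA	ZFN+GFP		8h	blastocyst	11	93	12
DNA	ZFN+GFP		8h	green	0	10	0
DNA	ZFN+GFP		8h	mutated	5	7	71
DNA	ZFN+GFP		18h	blastocyst	10	89	11
DNA	ZFN+GFP		18h	green	0	10	0
DNA	ZFN+GFP		18h	mutated	5	6	83
RNA	ZFN+GFP		8h	blastocyst	25	89	28
RNA	ZFN+GFP		8h	green	25	25	100
RNA	ZFN+GFP		8h	mutated	7	10	70
RNA	ZFN+GFP		18h	blastocyst	33	90	37
RNA	ZFN+GFP		18h	green	33	33	100
RNA	ZFN+GFP		18h	mutated	2	7	29
DNA	ZFN-FL	970	8h	tm_bl	11	110	10
DNA	ZFN-FL	970	8h	mutated	2	11	18
DNA	ZFN-FL	970	18h	tm_bl	37	252	15
DNA	ZFN-FL	970	18h	mutated	6	18	33
DNA	ZFN-FL	986	8h	tm_bl	16	99	16
DNA	ZFN-FL	986	8h	mutated	4	12	33
DNA	ZFN-FL	986	18h	tm_bl	17	89	19
DNA	ZFN-FL	986	18h	mutated	4	15	27
RNA	ZFN	986	8h	tm_bl	17	139	12
RNA	ZFN	986	8h	mutated	2	17	12
RNA	ZFN	986	18h	tm_bl	10	110	9
RNA	ZFN	986	18h	mutated	4	10	40
DNA	btBLG1.1	986	18h	blastocyst	22	50	44
DNA	btBLG1.1	986	18h	mutated	2	5	40
DNA	btBLG1.2	986	18h	blastocyst	84	269	31
DNA	btBLG1.2	986	18h	mutated	22	48	46
RNA	btBLG1.2	986	18h	blastocyst	37	127	29
RNA	btBLG1.2	986	18h	mutated	4	35	11
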