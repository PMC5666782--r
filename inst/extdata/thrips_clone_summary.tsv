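species	gene	individual_id	sex	n_clones	n_haplotypes	dominant_freq_pct
SD	mtCO1	SD-1	F	33	4	90.9
SD	mtCO1	SD-2	F	44	11	77.2
SD	mtCO1	SD-3	M	24	4	87.5
SD	mtCO1	SD-4	M	31	5	87.0
SD	ITS2	SD-1	F	23	17	21.7
SD	ITS2	SD-2	F	26	19	23.0
SD	ITS2	SD-3	M	42	21	33.3
SD	ITS2	SD-4	M	46	19	26.0
TP	mtCO1	TP-1	F	42	5	90.4
TP	mtCO1	TP-2	F	24	3	91.6
TP	mtCO1	TP-3	M	24	1	100
TP	mtCO1	TP-4	M	30	4	90
TP	ITS2	TP-1	F	41	23	24.3
TP	ITS2	TP-2	F	38	18	18.4
TP	ITS2	TP-3	M	31	16	22.5
TP	ITS2	TP-4	M	39	28	15.3
FO	mtCO1	FO-1	F	42	6	85.7
FO	mtCO1	FO-2	F	31	4	87.0
FO	mtCO1	FO-3	M	46	5	86.9
FO	mtCO1	FO-4	M	31	2	96.7
FO	ITS2	FO-1	F	20	4	85
FO	ITS2	FO-2	F	17	2	94.1
FO	ITS2	FO-3	M	36	7	83.3
FO	ITS2	FO-4	M	32	3	93.7
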