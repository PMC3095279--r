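gene1	gene2	species	conserved_flanking	mean_ks	date_ma
PtPLD10	PtPLD4	Poplar	7	0.2120	11.65
PtPLD17	PtPLD15	Poplar	2	0.2059	11.31
PtPLD6	PtPLD3	Poplar	12	0.2451	13.47
PtPLD13	PtPLD2	Poplar	5	0.2505	13.76
PtPLD16	PtPLD8	Poplar	6	0.2274	12.49
OsPLDb1	OsPLDb2	Rice	3	0.9023	69.41
OsPLDa1	OsPLDa2	Rice	3	0.9971	76.70
OsPLDd2	OsPLDd3	Rice	1	0.9190	70.69
VvPLD10	VvPLD1	Grape	3	1.1491	88.39
AtPLDa1	AtPLDa2	Arabidopsis	3	0.7527	25.09
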