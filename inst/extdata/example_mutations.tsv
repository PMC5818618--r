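patient_id	gene	variant_class
P01	NFE2L2	Missense_Mutation
P02	KEAP1	Missense_Mutation
P03	NFE2L2	Missense_Mutation
P04	KEAP1	Missense_Mutation
P05	NFE2L2	Missense_Mutation
P06	KEAP1	Missense_Mutation
P07	NFE2L2	Missense_Mutation
P08	KEAP1	Missense_Mutation
P09	NFE2L2	Missense_Mutation
P10	KEAP1	Missense_Mutation
P11	NFE2L2	Missense_Mutation
P12	KEAP1	Missense_Mutation
P13	NFE2L2	Missense_Mutation
P14	KEAP1	Missense_Mutation
P15	NFE2L2	Missense_Mutation
P16	KEAP1	Missense_Mutation
P17	NFE2L2	Missense_Mutation
P18	KEAP1	Missense_Mutation
P19	NFE2L2	Missense_Mutation
P20	KEAP1	Missense_Mutation
P21	NFE2L2	Missense_Mutation
P01	TP53	Missense_Mutation
P02	TP53	Missense_Mutation
P03	TP53	Missense_Mutation
P04	TP53	Missense_Mutation
P05	TP53	Missense_Mutation
P06	TP53	Missense_Mutation
P07	TP53	Nonsense_Mutation
P08	TP53	Missense_Mutation
P09	TP53	Missense_Mutation
P10	TP53	Missense_Mutation
P11	TP53	Missense_Mutation
P12	TP53	Missense_Mutation
P13	TP53	Missense_Mutation
P14	TP53	Nonsense_Mutation
P15	TP53	Missense_Mutation
P16	TP53	Missense_Mutation
P17	TP53	Missense_Mutation
P18	TP53	Missense_Mutation
P19	TP53	Missense_Mutation
P20	TP53	Missense_Mutation
P21	TP53	Nonsense_Mutation
P22	TP53	Missense_Mutation
P23	TP53	Missense_Mutation
P24	TP53	Missense_Mutation
P25	TP53	Missense_Mutation
P26	TP53	Missense_Mutation
P27	TP53	Missense_Mutation
P28	TP53	Nonsense_Mutation
P29	TP53	Missense_Mutation
P30	TP53	Missense_Mutation
P31	TP53	Missense_Mutation
P32	TP53	Missense_Mutation
P33	TP53	Missense_Mutation
P34	TP53	Missense_Mutation
P35	TP53	Nonsense_Mutation
P36	TP53	Missense_Mutation
P37	TP53	Missense_Mutation
P38	TP53	Missense_Mutation
P39	TP53	Missense_Mutation
P40	TP53	Missense_Mutation
P41	TP53	Missense_Mutation
P42	TP53	Nonsense_Mutation
P43	TP53	Missense_Mutation
P44	TP53	Missense_Mutation
P45	TP53	Missense_Mutation
P46	TP53	Missense_Mutation
P01	PTEN	Missense_Mutation
P02	RB1	Missense_Mutation
P03	PIK3CA	Missense_Mutation
P04	PTEN	Missense_Mutation
P05	RB1	Missense_Mutation
P06	PIK3CA	Missense_Mutation
P07	PTEN	Missense_Mutation
P08	RB1	Missense_Mutation
P09	PIK3CA	Missense_Mutation
P10	PTEN	Missense_Mutation
P11	RB1	Missense_Mutation
P12	PIK3CA	Missense_Mutation
P13	PTEN	Missense_Mutation
P14	RB1	Missense_Mutation
P15	PIK3CA	Missense_Mutation
P16	PTEN	Missense_Mutation
P17	RB1	Missense_Mutation
P18	PIK3CA	Missense_Mutation
P19	PTEN	Missense_Mutation
P20	RB1	Missense_Mutation
P21	PIK3CA	Missense_Mutation
P22	PTEN	Missense_Mutation
P23	RB1	Missense_Mutation
P24	PIK3CA	Missense_Mutation
P25	PTEN	Missense_Mutation
P26	RB1	Missense_Mutation
P27	PIK3CA	Missense_Mutation
P28	PTEN	Missense_Mutation
P29	RB1	Missense_Mutation
P30	PIK3CA	Missense_Mutation
P31	PTEN	Missense_Mutation
P32	RB1	Missense_Mutation
P01	SOX2	Missense_Mutation
P02	SOX2	Missense_Mutation
P03	SOX2	Missense_Mutation
P04	SOX2	Missense_Mutation
P05	SOX2	Missense_Mutation
P06	SOX2	Missense_Mutation
P07	SOX2	Missense_Mutation
P08	SOX2	Missense_Mutation
P09	SOX2	Missense_Mutation
P10	SOX2	Missense_Mutation
P11	SOX2	Missense_Mutation
P12	SOX2	Missense_Mutation
P13	SOX2	Missense_Mutation
P14	SOX2	Missense_Mutation
P01	MLL2	Missense_Mutation
P02	MLL2	Missense_Mutation
P03	MLL2	Missense_Mutation
P04	MLL2	Missense_Mutation
P05	MLL2	Frame_Shift_Del
P06	MLL2	Missense_Mutation
P07	MLL2	Missense_Mutation
P08	MLL2	Missense_Mutation
P09	MLL2	Missense_Mutation
P10	MLL2	Frame_Shift_Del
P11	MLL2	Missense_Mutation
P12	MLL2	Missense_Mutation
P13	MLL2	Missense_Mutation
P14	MLL2	Missense_Mutation
P15	MLL2	Frame_Shift_Del
P16	MLL2	Missense_Mutation
P17	MLL2	Missense_Mutation
P18	MLL2	Missense_Mutation
P19	MLL2	Missense_Mutation
P20	MLL2	Frame_Shift_Del
P21	MLL2	Missense_Mutation
P22	MLL2	Missense_Mutation
P23	MLL2	Missense_Mutation
P24	MLL2	Missense_Mutation
P25	MLL2	Frame_Shift_Del
P26	MLL2	Missense_Mutation
P27	MLL2	Missense_Mutation
P28	MLL2	Missense_Mutation
P50	TP53	Silent
P55	KEAP1	Silent
P03	TP53	Missense_Mutation
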