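patient_id	time	event	stage	tmb	cyt	til_burden	til_clonality	immunogenicity
WE01	400	1	2	120	12	5.2	0.31	
WE02	150	1	3	40	3	1.1	0.12	
WE03	900	0	1	260	45	9.8	0.52	
WE04	620	1	2	90	8	3.3	0.27	
WE05	310	0	4	150	20	6.4	0.4	
WE06	75	1	3	30	2.5	0.9	0.08	
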