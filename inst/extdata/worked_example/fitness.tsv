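patient_id	immunogenicity	tumor_fitness	argmax_peptide	n_epitopes
WE01	5	0.2	WGAAAAAW	2
WE02	0			0
WE03	6.25	0.16	SIINFEKL	2
WE04	10	0.1	GILGFVFTM	2
WE05	2.21726e-36	4.51008e+35	YFNREQDHS	1
WE06	8	0.125	NLVPMVATM	1
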