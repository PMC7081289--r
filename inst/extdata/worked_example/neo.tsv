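patient_id	peptide_mt	peptide_wt	hla_allele	ic50_mt	ic50_wt
WE01	WGAAAAAW	WGAAATAW	HLA-A*02:01	100	1000
WE01	KLYEIFTEL	KLYEIFSEL	HLA-A*02:01	250	500
WE02	MPYERWLTC	MPYERWLSC	HLA-A*02:01	800	1600
WE02	HDWKNPRTC	HDWKNPRSC	HLA-A*02:01	5000	8000
WE03	SIINFEKL	SIINFEKV	HLA-A*02:01	50	500
WE03	QPRGHEDKW	QPRGHEDKW	HLA-A*02:01	400	800
WE04	GILGFVFTM	GILGFVFSM	HLA-A*02:01	150	1500
WE04	DERWQNKHY	DERWQNKHY	HLA-A*02:01	300	600
WE05	WWCHMDPGK	WWCHMDPGK	HLA-A*02:01	600	1200
WE05	YFNREQDHS	YFNREQDHS	HLA-A*02:01	450	900
WE06	NLVPMVATM	NLVPMVASM	HLA-A*02:01	80	640
WE06	TKGDERWHN	TKGDERWHN	HLA-A*02:01	9000	9000
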