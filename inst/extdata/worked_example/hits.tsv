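patient_id	peptide_mt	db_id	score	bitscore	evalue
WE01	WGAAAAAW	IEDB_GA	26	14.6234	0.0126783
WE01	WGAAAAAW	IEDB_FLU	6	6.91943	2.64359
WE01	WGAAAAAW	IEDB_CMV	4	6.14903	4.50928
WE01	WGAAAAAW	IEDB_EBV	4	6.14903	4.50928
WE01	KLYEIFTEL	IEDB_FLU	14	10.001	0.351312
WE01	KLYEIFTEL	IEDB_EBV	11	8.84543	0.782643
WE01	KLYEIFTEL	IEDB_NEF	10	8.46023	1.02216
WE01	KLYEIFTEL	IEDB_CMV	6	6.91943	2.97404
WE02	MPYERWLTC	IEDB_NEF	10	8.46023	1.02216
WE02	MPYERWLTC	IEDB_CMV	8	7.68983	1.74355
WE02	MPYERWLTC	IEDB_EBV	7	7.30463	2.27714
WE02	MPYERWLTC	IEDB_FLU	5	6.53423	3.88421
WE02	HDWKNPRTC	IEDB_CMV	7	7.30463	2.27714
WE02	HDWKNPRTC	IEDB_EBV	6	6.91943	2.97404
WE02	HDWKNPRTC	IEDB_NEF	6	6.91943	2.97404
WE02	HDWKNPRTC	IEDB_FLU	5	6.53423	3.88421
WE03	SIINFEKL	IEDB_NEF	38	19.2458	0.000514733
WE03	SIINFEKL	IEDB_EBV	12	9.23063	0.532665
WE03	SIINFEKL	IEDB_FLU	12	9.23063	0.532665
WE03	SIINFEKL	IEDB_CMV	6	6.91943	2.64359
WE03	QPRGHEDKW	IEDB_CMV	7	7.30463	2.27714
WE03	QPRGHEDKW	IEDB_NEF	7	7.30463	2.27714
WE03	QPRGHEDKW	IEDB_EBV	6	6.91943	2.97404
WE03	QPRGHEDKW	IEDB_FLU	6	6.91943	2.97404
WE03	QPRGHEDKW	IEDB_GA	6	6.91943	2.97404
WE04	GILGFVFTM	IEDB_FLU	43	21.1718	0.000152388
WE04	GILGFVFTM	IEDB_NEF	12	9.23063	0.599248
WE04	GILGFVFTM	IEDB_CMV	9	8.07503	1.33499
WE04	GILGFVFTM	IEDB_EBV	6	6.91943	2.97404
WE04	GILGFVFTM	IEDB_GA	6	6.91943	2.97404
WE04	DERWQNKHY	IEDB_NEF	7	7.30463	2.27714
WE04	DERWQNKHY	IEDB_CMV	6	6.91943	2.97404
WE04	DERWQNKHY	IEDB_EBV	5	6.53423	3.88421
WE04	DERWQNKHY	IEDB_FLU	3	5.76383	6.62547
WE05	WWCHMDPGK	IEDB_CMV	7	7.30463	2.27714
WE05	WWCHMDPGK	IEDB_FLU	6	6.91943	2.97404
WE05	WWCHMDPGK	IEDB_GA	6	6.91943	2.97404
WE05	WWCHMDPGK	IEDB_EBV	5	6.53423	3.88421
WE05	WWCHMDPGK	IEDB_NEF	5	6.53423	3.88421
WE05	YFNREQDHS	IEDB_NEF	9	8.07503	1.33499
WE05	YFNREQDHS	IEDB_EBV	7	7.30463	2.27714
WE05	YFNREQDHS	IEDB_CMV	6	6.91943	2.97404
WE05	YFNREQDHS	IEDB_FLU	6	6.91943	2.97404
WE06	NLVPMVATM	IEDB_CMV	40	20.0162	0.000339486
WE06	NLVPMVATM	IEDB_FLU	10	8.46023	1.02216
WE06	NLVPMVATM	IEDB_NEF	6	6.91943	2.97404
WE06	NLVPMVATM	IEDB_EBV	5	6.53423	3.88421
WE06	NLVPMVATM	IEDB_GA	4	6.14903	5.07294
WE06	TKGDERWHN	IEDB_NEF	7	7.30463	2.27714
WE06	TKGDERWHN	IEDB_CMV	6	6.91943	2.97404
WE06	TKGDERWHN	IEDB_FLU	6	6.91943	2.97404
WE06	TKGDERWHN	IEDB_GA	6	6.91943	2.97404
WE06	TKGDERWHN	IEDB_EBV	5	6.53423	3.88421
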