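cell_line	mirna	mirna_dir	gene	gene_dir
786-O	hsa-miR-663a	up	CDKN1A	down
786-O	hsa-miR-572	up	CDKN1A	down
786-O	hsa-miR-638	up	PTEN	down
786-O	hsa-miR-612	up	SP1	down
786-O	hsa-miR-212-3p	up	RFXAP	down
786-O	hsa-miR-106a-5p	down	SIRPA	up
786-O	hsa-miR-106a-5p	down	MMP2	up
786-O	hsa-miR-106a-5p	down	HIF1A	up
786-O	hsa-miR-30d-5p	down	KPNB1	up
786-O	hsa-miR-30d-5p	down	BNIP3L	up
786-O	hsa-miR-30d-5p	down	BECN1	up
786-O	hsa-miR-140-3p	down	ATP6AP2	up
786-O	hsa-miR-140-3p	down	FN1	up
786-O	hsa-miR-26b-5p	down	PTGS2	up
786-O	hsa-miR-26b-5p	down	ST8SIA4	up
786-O	hsa-miR-17-5p	down	MMP2	up
786-O	hsa-miR-17-5p	down	SIRPA	up
786-O	hsa-miR-17-5p	down	GPR137B	up
786-O	hsa-miR-17-5p	down	EPAS1	up
786-O	hsa-miR-17-5p	down	VLDLR	up
786-O	hsa-miR-17-5p	down	HIF1A	up
786-O	hsa-miR-200a-3p	down	WASF3	up
786-O	hsa-miR-200a-3p	down	CD274	up
786-O	hsa-miR-200b-3p	down	LOX	up
786-O	hsa-miR-200b-3p	down	FN1	up
786-O	hsa-miR-200b-3p	down	CD274	up
786-O	hsa-miR-200b-3p	down	WASF3	up
786-O	hsa-miR-200b-3p	down	MSN	up
786-O	hsa-miR-200b-3p	down	FERMT2	up
786-O	hsa-miR-200b-3p	down	FSCN1	up
786-O	hsa-miR-200b-3p	down	RAB23	up
786-O	hsa-miR-210-3p	down	HIF1A	up
786-O	hsa-miR-210-3p	down	BDNF	up
786-O	hsa-miR-210-3p	down	NCAM1	up
786-O	hsa-miR-210-3p	down	EHD2	up
786-O	hsa-miR-210-3p	down	TFRC	up
786-O	hsa-miR-328-3p	down	PTPRJ	up
786-O	hsa-miR-328-3p	down	MMP16	up
786-O	hsa-miR-34a-5p	down	BECN1	up
786-O	hsa-miR-34a-5p	down	VAMP2	up
786-O	hsa-miR-34a-5p	down	FUT8	up
786-O	hsa-miR-34a-5p	down	INHBB	up
786-O	hsa-miR-34a-5p	down	NOTCH2	up
786-O	hsa-miR-34a-5p	down	MAGEA2	up
786-O	hsa-miR-34a-5p	down	MAGEA3	up
786-O	hsa-miR-34a-5p	down	L1CAM	up
786-O	hsa-miR-34a-5p	down	AXL	up
786-O	hsa-miR-34a-5p	down	PAM	up
786-O	hsa-miR-34a-5p	down	SYT1	up
786-O	hsa-miR-34a-5p	down	CD274	up
786-O	hsa-miR-21-5p	down	BASP1	up
786-O	hsa-miR-21-5p	down	RECK	up
786-O	hsa-miR-21-5p	down	NFIB	up
786-O	hsa-miR-21-5p	down	SATB1	up
786-O	hsa-miR-21-5p	down	RHOB	up
786-O	hsa-miR-21-5p	down	PIAS3	up
786-O	hsa-miR-21-5p	down	DUSP10	up
786-O	hsa-miR-21-5p	down	LRP6	up
786-O	hsa-miR-146a-5p	down	L1CAM	up
786-O	hsa-miR-146a-5p	down	NOTCH2	up
786-O	hsa-miR-146a-5p	down	PTGS2	up
786-O	hsa-miR-146a-5p	down	HOXD10	up
786-O	hsa-miR-146a-5p	down	RAC1	up
786-O	hsa-miR-20a-5p	down	SIRPA	up
786-O	hsa-miR-20a-5p	down	EPAS1	up
786-O	hsa-miR-20a-5p	down	KIF26B	up
786-O	hsa-miR-20a-5p	down	CRIM1	up
786-O	hsa-miR-20a-5p	down	HIF1A	up
786-O	hsa-miR-20a-5p	down	TSG101	up
786-O	hsa-miR-17-3p	down	ITGA5	up
786-O	hsa-miR-17-3p	down	ITGB3	up
786-O	hsa-miR-99a-5p	down	SMARCA5	up
786-O	hsa-miR-18a-5p	down	PIAS3	up
786-O	hsa-miR-18a-5p	down	TNFAIP3	up
786-O	hsa-miR-18a-5p	down	HIF1A	up
786-O	hsa-miR-18a-5p	down	TBPL1	up
786-O	hsa-miR-25-5p	down	PRKCZ	up
A498	hsa-miR-34c-5p	up	ITPR1	down
A498	hsa-miR-34c-5p	up	HNF4A	down
A498	hsa-miR-145-5p	down	ITGB8	up
A498	hsa-miR-145-5p	down	CTGFL	up
A498	hsa-miR-145-5p	down	VPS51	up
A498	hsa-miR-145-5p	down	EGFR	up
Caki-1	hsa-miR-148b-3p	up	SLC2A1	down
Caki-1	hsa-miR-192-5p	up	ITGB3	down
Caki-1	hsa-miR-192-5p	up	ITGAV	down
Caki-1	hsa-miR-192-5p	up	CAV1	down
Caki-1	hsa-miR-192-5p	up	WNK1	down
Caki-1	hsa-miR-29b-3p	up	DNMT3B	down
Caki-1	hsa-miR-138-5p	down	CCND1	up
Caki-1	hsa-miR-193b-3p	down	CCND1	up
Caki-1	hsa-miR-193b-3p	down	AKR1C2	up
Caki-1	hsa-miR-92a-5p	down	KLF2	up
Caki-1	hsa-miR-296-3p	down	ICAM1	up
Caki-1	hsa-miR-106b-5p	down	BMP2	up
Caki-1	hsa-miR-106b-5p	down	RND3	up
Caki-1	hsa-miR-106b-5p	down	CCND1	up
Caki-1	hsa-miR-106b-3p	down	BMP2	up
Caki-1	hsa-miR-130b-3p	down	IRF1	up
Caki-1	hsa-miR-708-5p	down	CCND1	up
Caki-1	hsa-miR-18a-5p	down	TNFAIP3	up
Caki-1	hsa-miR-18a-5p	down	CTGF	up
Caki-1	hsa-miR-17-5p	down	CCND1	up
Caki-1	hsa-miR-17-5p	down	BMP2	up
Caki-1	hsa-miR-17-5p	down	TCEAL1	up
Caki-1	hsa-miR-17-5p	down	RND3	up
Caki-1	hsa-miR-1180-3p	down	TCEAL1	up
Caki-1	hsa-miR-550a-5p	down	CPEB4	up
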