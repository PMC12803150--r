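id	ligand	receptor	pathway	agonist	antagonist
COL1_ITGA	colA1	itgA1+itgB1	Collagen
COL2_ITGA	colA2	itgA1+itgB1	Collagen
COL3_ITGB	colA3	itgA2+itgB1	Collagen
COL4_DDR	colA4	ddrX1	Collagen
COL5_DDR	colA5	ddrX2	Collagen
MMP1_TIMP	mmpL1	mmpR1	MMP		timpX1
MMP2_TIMP	mmpL2	mmpR1	MMP		timpX1
MMP3_R2	mmpL3	mmpR2	MMP
MMP4_R2	mmpL4	mmpR2	MMP
SLIT1_ROBO1	slitL1	roboR1	SlitRobo
SLIT1_ROBO2	slitL1	roboR2	SlitRobo
SLIT2_ROBO1	slitL2	roboR1	SlitRobo
SLIT2_ROBO2	slitL2	roboR2	SlitRobo
SPP1_CD44	sppL1	cd44R	SPP1
SPP1_ITGAV	sppL1	itgAV+itgB3	SPP1
SPP2_CD44	sppL2	cd44R	SPP1
SEMA1_PLXN1	semaL1	plxnR1	Semaphorin
SEMA1_PLXN2	semaL1	plxnR2	Semaphorin
SEMA2_PLXN1	semaL2	plxnR1	Semaphorin
SEMA2_NRP	semaL2	nrpR1+plxnR1	Semaphorin
NOTCH_DLL1	dllL1	notchR1	Notch	jagAG1
NOTCH_DLL2	dllL2	notchR1	Notch	jagAG1
NOTCH_JAG1	jagL1	notchR2	Notch
NOTCH_JAG2	jagL2	notchR2	Notch
BMP2_R1A	bmpL2	bmprR1A+bmprR2	BMP		nogANT1
BMP4_R1A	bmpL4	bmprR1A+bmprR2	BMP		nogANT1
BMP4_R1B	bmpL4	bmprR1B+bmprR2	BMP		nogANT1
BMP7_R1B	bmpL7	bmprR1B+bmprR2	BMP
BMP6_R1A	bmpL6	bmprR1A+bmprR2	BMP
BMP2_R1B	bmpL2	bmprR1B+bmprR2	BMP
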