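ligand	receptor
TNFSF12	TNFRSF12A
LAMA1	RPSA
LAMB1	RPSA
EGF	EGFR
HBEGF	EGFR
TGFA	EGFR
AREG	EGFR
FGF2	FGFR4
FGF6	FGFR4
DLL4	NOTCH3
JAG1	NOTCH3
HGF	MET
IGF1	IGF1R
VEGFA	KDR
VEGFC	FLT4
CCL2	CCR2
CXCL12	CXCR4
COL1A1	ITGB1
FN1	ITGB1
LGALS1	CD44
SPP1	CD44
TNF	TNFRSF1A
IL6	IL6R
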