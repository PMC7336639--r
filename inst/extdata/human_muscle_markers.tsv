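cell_type	markers
MuSC	PAX7,MYF5,CHRDL2,DLK1
Myonuclei	ACTA1,TNNC2,MYLPF
Fibroblast	PDGFRA,COL1A1,DCN
Adipocyte	ADIPOQ,PLIN1
Pericyte	RGS5,PDGFRB
SmoothMuscle	MYH11,ACTA2
Endothelial	PECAM1,VWF,CDH5
LymphaticEC	PROX1,LYVE1
Macrophage	CD14,LYZ,CD68
Tcell	CD3E,CD2
Bcell	CD79A,MS4A1
NKcell	NKG7,GNLY
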