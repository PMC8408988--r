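interferon_gamma_signalling	synthetic placeholder set	IFNG	IFNGR1	IFNGR2	JAK1	JAK2	STAT1	IRF1	IRF9	GBP1	GBP2	CXCL9	CXCL10	CXCL11	IDO1
pd_l_blockade	synthetic placeholder set	CD274	PDCD1	PDCD1LG2	CD80	CD8A	LCK	ZAP70	CD3E	CD3D	CD247	PTPN11
ctla4_pathway	synthetic placeholder set	CTLA4	CD28	CD80	CD86	ICOS	CD3E	CD3G	LCK	FYN	PIK3CD
cd28_costimulation	synthetic placeholder set	CD28	CD86	GRB2	VAV1	PIK3R1	PIK3CD	AKT1	MAP3K8	RLTPR
nk_cytotoxicity	synthetic placeholder set	KLRK1	NCR1	NCR3	PRF1	GZMB	GZMA	FCGR3A	KIR2DL1	KLRD1	SH2D1B	TYROBP
antigen_processing_presentation	synthetic placeholder set	HLA-A	HLA-B	HLA-C	B2M	TAP1	TAP2	TAPBP	PSMB8	PSMB9	ERAP1	CALR
jak_stat_signalling	synthetic placeholder set	JAK1	JAK2	JAK3	TYK2	STAT1	STAT2	STAT3	STAT4	STAT5A	STAT5B	SOCS1	IL6R
il2_stat4_5	synthetic placeholder set	IL2	IL2RA	IL2RB	IL2RG	STAT4	STAT5A	STAT5B	IL12A	IL12B	IL12RB1	IL12RB2
cd8_effector	synthetic placeholder set	CD8A	CD8B	GZMB	GZMK	PRF1	IFNG	EOMES	TBX21	KLRG1	CX3CR1	FASLG
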