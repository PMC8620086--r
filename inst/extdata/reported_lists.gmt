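mutual14	genes mutual to all five compared condition networks	INS	INSR	EDN1	EPO	ADIPOQ	IL1B	IL6	TNF	GLP1R	IGF1	VEGFA	CRP	NFE2L2	NPY
endothelial_in_network	microvascular-endothelium genes present in the focus network	CD36	CLDN5	EGFR	FGF2	INSR	LEP	LEPR	NOTCH1	SLC16A1	SLC22A1	SLC2A1	SLC5A1	TNF	TRAF6	VEGFA
top_cts10	ten genes with the highest cross-talk specificity	GPR142	MBOAT4	SLC5A4	IGFBP6	PPY	G6PC1	SLC2A2	GYS2	GCGR	AQP7
hub_genes	junction genes with over 100 network connections and top betweenness	INS	IL6	LEP	TNF	IL1B	EGFR	FOS
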