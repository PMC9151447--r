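t_cells	canonical T-cell markers	CD3D	CD3E	CD3G	CD28	TRAC
cd8_t_cells	CD8 T-cell markers	CD8A	CD8B
cytotoxic_lymphocytes	cytotoxicity markers	GZMA	GZMB	PRF1	KLRD1	NKG7
b_lineage	B-lineage markers	CD19	MS4A1	CD79A	CD79B	IGKC
nk_cells	NK-cell markers	NCR1	KIR2DL3	NKp46	KLRC1
monocytic_lineage	monocyte/macrophage markers	CD14	CD163	CSF1R	ITGAM
myeloid_dendritic_cells	myeloid dendritic markers	CD1A	CD1B	CLEC10A	FCER1A
neutrophils	neutrophil markers	FCGR3B	CSF3R	CEACAM3	S100A12
endothelial_cells	endothelial markers	PECAM1	VWF	CDH5	CLDN5
fibroblasts	fibroblast markers	COL1A1	COL3A1	DCN	PDGFRB
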