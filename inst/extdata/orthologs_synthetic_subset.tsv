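# Synthetic demonstration subset of human->mouse gene symbol orthologs.
# Hand-assembled for examples and tests; NOT a BioMart export. For real
# analyses supply a full ortholog table (e.g. an Ensembl BioMart download)
# via read_ortholog_table().
human_symbol	mouse_symbol
CD2	Cd2
CD3D	Cd3d
CD3E	Cd3e
CD3G	Cd3g
CD4	Cd4
CD8A	Cd8a
CD8B	Cd8b1
PDCD1	Pdcd1
PDCD1LG2	Pdcd1lg2
CTLA4	Ctla4
LAG3	Lag3
HAVCR2	Havcr2
TIGIT	Tigit
ENTPD1	Entpd1
TOX	Tox
TOX2	Tox2
TCF7	Tcf7
LEF1	Lef1
SELL	Sell
CCR7	Ccr7
IL7R	Il7r
CXCR3	Cxcr3
CXCR5	Cxcr5
CX3CR1	Cx3cr1
XCL1	Xcl1
GZMA	Gzma
GZMB	Gzmb
GZMK	Gzmk
PRF1	Prf1
IFNG	Ifng
TNFRSF9	Tnfrsf9
TNFRSF4	Tnfrsf4
TNFSF4	Tnfsf4
FOXP3	Foxp3
IL2RA	Il2ra
IKZF2	Ikzf2
KLRG1	Klrg1
KLRC1	Klrc1
SLAMF6	Slamf6
CCL5	Ccl5
NKG7	Nkg7
MKI67	Mki67
TOP2A	Top2a
CD40LG	Cd40lg
ANXA1	Anxa1
RORA	Rora
TBC1D4	Tbc1d4
FASLG	Fasl
IFNGR1	Ifngr1
SPI1	Spi1
FCER1G	Fcer1g
CSF1R	Csf1r
CD19	Cd19
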