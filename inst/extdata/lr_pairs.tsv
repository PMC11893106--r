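pair_id	ligand	receptor	pathway_label
WNT4_FZD3_LRP6	Wnt4	Fzd3;Lrp6	WNT
WNT5A_FZD1_LRP6	Wnt5a	Fzd1;Lrp6	WNT
RSPO1_LGR4	Rspo1	Lgr4	WNT
BMP2_BMPR1A_ACVR2B	Bmp2	Bmpr1a;Acvr2b	BMP
BMP7_BMPR1B_ACVR2A	Bmp7	Bmpr1b;Acvr2a	BMP
INHA_ACVR1B_ACVR2B	Inha	Acvr1b;Acvr2b	inhibin/activin
INHBA_ACVR1B_ACVR2A	Inhba	Acvr1b;Acvr2a	inhibin/activin
FGF9_FGFR2	Fgf9	Fgfr2	FGF
DHH_PTCH1	Dhh	Ptch1	Hedgehog
KITL_KIT	Kitl	Kit	KIT
CXCL12_CXCR4	Cxcl12	Cxcr4	chemokine
AMH_AMHR2_ACVR1	Amh	Amhr2;Acvr1	TGFb
PDGFA_PDGFRA	Pdgfa	Pdgfra	PDGF
IGF1_IGF1R	Igf1	Igf1r	IGF
NODAL_ACVR1B_TDGF1	Nodal	Acvr1b;Tdgf1	TGFb
JAG1_NOTCH2	Jag1	Notch2	Notch
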