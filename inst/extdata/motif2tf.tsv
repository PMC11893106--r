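motif_id	tf_name	tf_gene
MA9001.1	TFAP2C	Tfap2c
MA9002.1	FOXK2	Foxk2
MA9003.1	TCFL5	Tcfl5
MA9004.1	ZFX	Zfx
MA9005.1	POU6F2	Pou6f2
MA9006.1	NR6A1	Nr6a1
MA9007.1	GATA2	Gata2
MA9008.1	MGA	Mga
MA9009.1	RREB1	Rreb1
MA9010.1	DMRT1	Dmrt1
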