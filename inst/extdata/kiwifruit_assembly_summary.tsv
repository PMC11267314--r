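assembly	accession	group	n_genes
Biyu.hap1	Biyu	GF	46073
Biyu.hap2	Biyu	GF	46634
Hongyang.hap1	Hongyang	RF	45809
Hongyang.hap2	Hongyang	RF	45434
Hort16A.hap1	Hort16A	YF	44336
Hort16A.hap2	Hort16A	YF	46230
Huangyang.hap1	Huangyang	YF	45982
Huangyang.hap2	Huangyang	YF	45004
Jinmi.hap1	Jinmi	YF	45473
Jinmi.hap2	Jinmi	YF	45101
Jinpai.hap1	Jinpai	GF	46244
Jinpai.hap2	Jinpai	GF	45675
Zps18.hap1	Zps18	RF	45873
Zps18.hap2	Zps18	RF	45481
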