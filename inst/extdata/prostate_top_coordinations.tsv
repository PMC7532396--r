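enhancer_id	tf_name	erna_probe_id	gene_id
K562_enhancer_301676	FOSL2	ENST00000448942	TNFAIP3
K562_enhancer_301676	USF2	ENST00000448942	TNFAIP3
K562_enhancer_301676	KLF5	ENST00000448942	TNFAIP3
K562_enhancer_301676	ZEB1	ENST00000448942	TNFAIP3
K562_enhancer_301676	EGR1	ENST00000448942	TNFAIP3
K562_enhancer_301676	JUND	ENST00000448942	TNFAIP3
K562_enhancer_301676	JUNB	ENST00000448942	TNFAIP3
K562_enhancer_301676	MITF	ENST00000448942	TNFAIP3
K562_enhancer_301676	CTCFL	ENST00000448942	TNFAIP3
K562_enhancer_301676	FOSL1	ENST00000448942	TNFAIP3
K562_enhancer_301676	EBF1	ENST00000448942	TNFAIP3
K562_enhancer_301676	CREB1	ENST00000448942	TNFAIP3
K562_enhancer_301676	MITF	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	JUND	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	NFKB1	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	KLF5	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	ZEB1	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	FOSL2	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	EGR1	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	USF2	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	FOSL1	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	CTCFL	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	EBF1	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	CREB1	lnc-PERP-2:25	TNFAIP3
K562_enhancer_301676	JUNB	lnc-PERP-2:25	TNFAIP3
K562_enhancer_288447	NRF1	NR_146633	SUPT3H
K562_enhancer_288447	ELK4	NR_146633	SUPT3H
K562_enhancer_288447	AR	NR_146633	SUPT3H
K562_enhancer_288447	EGR1	NR_146633	SUPT3H
K562_enhancer_288447	ZNF384	NR_146633	SUPT3H
K562_enhancer_288447	MYCN	NR_146633	SUPT3H
K562_enhancer_288447	ZBTB7A	NR_146633	SUPT3H
K562_enhancer_288447	KLF9	NR_146633	SUPT3H
K562_enhancer_288447	KLF5	NR_146633	SUPT3H
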