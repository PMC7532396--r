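erna_accession	erna_p	erna_fc	erna_regulation	target_gene	gene_p	gene_fc	gene_regulation
ENST00000624982	0.027	21.56	Down	IL10RA	0.046	2.76	Down
ENST00000458250	0.041	20.57	Down	HSD11B1	0.004	5.14	Down
ENST00000603283	0.020	19.88	Down	LAMB3	0.024	14.53	Down
lnc-SEL1L2-3:1	0.013	17.27	Down	FLRT3	0.008	17.09	Down
ENST00000504829	0.024	14.75	Down	SNCAIP	0.037	6.80	Down
NONHSAT252076	0.014	8.94	Up	HIST1H1T	0.037	8.79	Up
NONHSAT219894	0.008	6.12	Up	CORO2A	0.025	2.11	Up
NONHSAT175755	0.030	4.68	Up	SLC25A10	0.007	2.64	Up
NONHSAT056617	0.001	4.60	Up	FASN	0.022	5.44	Up
NONHSAT233757	0.025	4.40	Up	PLEKHH1	0.046	3.37	Up
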