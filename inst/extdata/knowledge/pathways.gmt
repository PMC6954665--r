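PI3K_Akt_signaling	PI3K-Akt signaling pathway	PIK3CA|1|activator	PIK3R1|1|activator	AKT1|1|activator	AKT2|1|activator	MTOR|1|activator	PDPK1|1|activator	RPS6KB1|1|activator	GSK3B|1|activator	PTEN|-1|inhibitor	FOXO3|-1|inhibitor	TSC1|-1|inhibitor	INPP4B|-1|inhibitor
MAPK_signaling	MAPK signaling pathway	BRAF|1|activator	KRAS|1|activator	NRAS|1|activator	HRAS|1|activator	RAF1|1|activator	MAP2K1|1|activator	MAP2K2|1|activator	MAPK1|1|activator	MAPK3|1|activator	EGFR|1|activator	DUSP6|-1|inhibitor	NF1|-1|inhibitor
Cell_cycle	Cell cycle	CDK4|1|activator	CDK6|1|activator	CCND1|1|activator	CCNE1|1|activator	CDK2|1|activator	E2F1|1|activator	MYC|1|activator	PLK1|1|activator	AURKA|1|activator	RB1|-1|inhibitor	CDKN1A|-1|inhibitor	CDKN2A|-1|inhibitor
p53_signaling	p53 signaling pathway	TP53|1|activator	CDKN1A|1|activator	BAX|1|activator	BBC3|1|activator	GADD45A|1|activator	CHEK2|1|activator	ATM|1|activator	TP53BP1|1|activator	MDM2|-1|inhibitor	MDM4|-1|inhibitor
Estrogen_signaling	Estrogen signaling pathway	ESR1|1|activator	ESR2|1|activator	PGR|1|activator	AR|1|activator	NCOA3|1|activator	FOXA1|1|activator	GATA3|1|activator	GREB1|1|activator	TFF1|1|activator	APOBEC3B|1|activator
ErbB_signaling	ErbB signaling pathway	ERBB2|1|activator	ERBB3|1|activator	ERBB4|1|activator	EGFR|1|activator	GRB2|1|activator	SHC1|1|activator	SOS1|1|activator	NRG1|1|activator	CBL|-1|inhibitor
VEGF_signaling	VEGF signaling pathway	VEGFA|1|activator	VEGFB|1|activator	KDR|1|activator	FLT1|1|activator	FLT4|1|activator	NRP1|1|activator	HIF1A|1|activator	PGF|1|activator
Focal_adhesion	Focal adhesion	PTK2|1|activator	SRC|1|activator	ITGB1|1|activator	ITGA5|1|activator	FN1|1|activator	VCL|1|activator	PXN|1|activator	TLN1|1|activator	ACTN1|1|activator	ROCK1|1|activator
HIF1_signaling	HIF-1 signaling pathway	HIF1A|1|activator	EPAS1|1|activator	ARNT|1|activator	SLC2A1|1|activator	LDHA|1|activator	PGK1|1|activator	ENO1|1|activator	VHL|-1|inhibitor	EGLN1|-1|inhibitor
Wnt_signaling	Wnt signaling pathway	WNT1|1|activator	CTNNB1|1|activator	TCF7|1|activator	LEF1|1|activator	FZD1|1|activator	LRP6|1|activator	DVL1|1|activator	APC|-1|inhibitor	AXIN1|-1|inhibitor	GSK3B|-1|inhibitor
Notch_signaling	Notch signaling pathway	NOTCH1|1|activator	NOTCH2|1|activator	JAG1|1|activator	JAG2|1|activator	DLL1|1|activator	HES1|1|activator	HEY1|1|activator	RBPJ|1|activator	ADAM10|1|activator	NUMB|-1|inhibitor
Hedgehog_signaling	Hedgehog signaling pathway	SHH|1|activator	SMO|1|activator	GLI1|1|activator	GLI2|1|activator	IHH|1|activator	GLI3|1|activator	PTCH1|-1|inhibitor	SUFU|-1|inhibitor
JAK_STAT_signaling	JAK-STAT signaling pathway	JAK1|1|activator	JAK2|1|activator	STAT3|1|activator	STAT5A|1|activator	IL6|1|activator	IL6R|1|activator	STAT1|1|activator	TYK2|1|activator	SOCS1|-1|inhibitor	SOCS3|-1|inhibitor
TGF_beta_signaling	TGF-beta signaling pathway	TGFB1|1|activator	TGFBR1|1|activator	TGFBR2|1|activator	SMAD2|1|activator	SMAD3|1|activator	SMAD4|1|activator	THBS1|1|activator	SMAD7|-1|inhibitor	SKI|-1|inhibitor
mTOR_signaling	mTOR signaling pathway	MTOR|1|activator	RPTOR|1|activator	RICTOR|1|activator	RPS6KB1|1|activator	RHEB|1|activator	EIF4EBP1|-1|inhibitor	AKT1S1|-1|inhibitor	ULK1|-1|inhibitor	DEPTOR|-1|inhibitor
Apoptosis	Apoptosis	BAX|1|activator	BAK1|1|activator	CASP3|1|activator	CASP8|1|activator	CASP9|1|activator	TP53|1|activator	BID|1|activator	BCL2|-1|inhibitor	BCL2L1|-1|inhibitor	MCL1|-1|inhibitor
DNA_repair	DNA repair / homologous recombination	BRCA1|1|activator	BRCA2|1|activator	PARP1|1|activator	RAD51|1|activator	ATM|1|activator	ATR|1|activator	CHEK1|1|activator	CHEK2|1|activator	MLH1|1|activator	MSH2|1|activator	MSH6|1|activator	PMS2|1|activator	FANCA|1|activator	PALB2|1|activator	XRCC1|1|activator
NFkB_signaling	NF-kappa B signaling pathway	NFKB1|1|activator	RELA|1|activator	IKBKB|1|activator	CHUK|1|activator	TNF|1|activator	TRAF2|1|activator	TRAF6|1|activator	IKBKG|1|activator	NFKBIA|-1|inhibitor
Hippo_signaling	Hippo signaling pathway	YAP1|1|activator	WWTR1|1|activator	TEAD1|1|activator	TEAD4|1|activator	CCN2|1|activator	LATS1|-1|inhibitor	LATS2|-1|inhibitor	STK4|-1|inhibitor	SAV1|-1|inhibitor
Immune_checkpoint	Immune checkpoint signaling	PDCD1|1|activator	CD274|1|activator	PDCD1LG2|1|activator	CTLA4|1|activator	LAG3|1|activator	HAVCR2|1|activator	TIGIT|1|activator	IDO1|1|activator	CD80|1|activator	CD86|1|activator
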