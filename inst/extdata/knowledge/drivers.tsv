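gene_id	role	priority_weight	source_tag
PIK3CA	oncogene	3	curated-synthetic
TP53	tumor_suppressor	3	curated-synthetic
BRAF	oncogene	2.5	curated-synthetic
BRCA1	tumor_suppressor	2.5	curated-synthetic
BRCA2	tumor_suppressor	2.5	curated-synthetic
ERBB2	oncogene	2.5	curated-synthetic
KRAS	oncogene	2.5	curated-synthetic
PTEN	tumor_suppressor	2.5	curated-synthetic
RB1	tumor_suppressor	2.5	curated-synthetic
AKT1	oncogene	2	curated-synthetic
ATM	tumor_suppressor	2	curated-synthetic
CCND1	oncogene	2	curated-synthetic
CDH1	tumor_suppressor	2	curated-synthetic
EGFR	oncogene	2	curated-synthetic
ESR1	oncogene	2	curated-synthetic
GATA3	ambiguous	2	curated-synthetic
MYC	oncogene	2	curated-synthetic
NRAS	oncogene	2	curated-synthetic
ALK	oncogene	1.5	curated-synthetic
APC	tumor_suppressor	1.5	curated-synthetic
ARID1A	tumor_suppressor	1.5	curated-synthetic
CDK4	oncogene	1.5	curated-synthetic
CDKN2A	tumor_suppressor	1.5	curated-synthetic
CHEK2	tumor_suppressor	1.5	curated-synthetic
CTNNB1	oncogene	1.5	curated-synthetic
FGFR1	oncogene	1.5	curated-synthetic
FOXA1	oncogene	1.5	curated-synthetic
JAK2	oncogene	1.5	curated-synthetic
KIT	oncogene	1.5	curated-synthetic
MDM2	oncogene	1.5	curated-synthetic
MET	oncogene	1.5	curated-synthetic
MLH1	tumor_suppressor	1.5	curated-synthetic
MSH2	tumor_suppressor	1.5	curated-synthetic
NF1	tumor_suppressor	1.5	curated-synthetic
NOTCH1	ambiguous	1.5	curated-synthetic
PALB2	tumor_suppressor	1.5	curated-synthetic
RET	oncogene	1.5	curated-synthetic
SMAD4	tumor_suppressor	1.5	curated-synthetic
STK11	tumor_suppressor	1.5	curated-synthetic
VHL	tumor_suppressor	1.5	curated-synthetic
AURKA	oncogene	1	curated-synthetic
KMT2C	tumor_suppressor	1	curated-synthetic
RUNX1	ambiguous	1	curated-synthetic
STAT3	ambiguous	1	curated-synthetic
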