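# Curated gene lists consumed by the immunotherapy and pharmacogenomics
# stages. Members use HGNC symbols from the bundled cross-reference.
dna_repair:
  - BRCA1
  - BRCA2
  - ATM
  - ATR
  - MLH1
  - MSH2
  - MSH6
  - PMS2
  - PARP1
  - RAD51
  - CHEK1
  - CHEK2
  - PALB2
  - FANCA
  - XRCC1
checkpoint_biomarkers:
  - PDCD1
  - CD274
  - PDCD1LG2
  - CTLA4
  - LAG3
  - HAVCR2
  - TIGIT
  - IDO1
efflux_transporters:
  - ABCB1
  - ABCC1
  - ABCC2
  - ABCG2
drug_metabolizing_enzymes:
  - CYP2D6
  - CYP3A4
  - CYP3A5
  - CYP2C9
  - CYP2C19
  - CYP19A1
  - UGT1A1
  - DPYD
  - TPMT
  - SULT1A1
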