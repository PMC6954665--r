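# molboard

Headless molecular-tumor-board analytics for a single breast tumor
sample. molboard integrates the clinical markers an oncologist starts
from (ER/PR/HER2 status, menopausal status, grade, TNM, Ki-67) with the
tumor's expression, mutation, copy-number and promoter-methylation data,
and derives the quantities a treatment-stratification discussion turns
on: driver events, pathway activities, the intrinsic subtype, tumor
mutational burden, and rule-based verdicts for standard-of-care and
off-label drugs. Everything is exposed as pipe-friendly R functions over
tibbles, with JSON exports for downstream visualization and a thin CLI
(`exec/molboard`) for shell use. It is a research tool: nothing in its
output is a treatment recommendation.

## The model in brief

* **Deregulation scores.** Per gene, differential expression versus the
  supplied controls: `log2((t + c)/(k + c))` against one control, or the
  z-score `(t − mean(k))/sd(k)` (sample sd) against several.
* **Pathway activity.** For each of 20 core cancer-relevant pathways with
  member weights `w_g` (+1 activator, −1 inhibitor), the raw score is the
  weighted sum `S = Σ_g w_g · d_g` over scored members. A permutation null
  (gene↦score assignment permuted over all scored genes, `n_perm` times)
  yields a two-sided empirical P-value
  `p = (1 + #{|S*| ≥ |S|})/(n_perm + 1)` with Benjamini–Hochberg
  adjustment across pathways, and a normalized activity in [0, 1] — the
  midrank position of `S` within its null. Labels: low [0, 0.4),
  medium [0.4, 0.6], high (0.6, 1].
* **Subtype.** PCA/t-SNE embedding with a labeled reference cohort on a
  cohort-standardized gene panel, plus a k-nearest-neighbour call (k = 15)
  over the four intrinsic subtypes (luminal A/B, HER2-enriched,
  basal-like).
* **Drivers.** Catalog-gated events graded severe / damaging / moderate
  from VeP-style impact, SIFT and PolyPhen; priority =
  catalog weight × severity points + extra altered channels.
* **Drugs.** 17 standard-of-care and 23 driver-targeting drugs evaluated
  by declarative rules (biomarkers, targets, metabolizing enzymes, efflux
  transporters, pathways); decisive contraindications (biomarker or
  enzyme) rule a drug out, balanced evidence yields *conditional*.
* **TMB.** Distinct somatic variants per megabase exon, with a midrank
  percentile against a cohort TMB vector, repair-gene impairment and a
  checkpoint-biomarker overview.

The methods vignette (`vignettes/treatment-stratification.Rmd`) documents
the formulas, defaults and design choices in full.

## Worked example

A complete synthetic case — a hormone-receptor-positive, HER2-negative,
premenopausal tumor carrying CYP2D6 and ESR2 frameshifts, BRCA1/2
germline variants, APOBEC3B/ERBB2/PARP1 upregulation and high MAPK
activity — is generated and analyzed in a few lines:

```r
library(molboard)

kb     <- load_knowledge_base()
gen    <- generate_case("case2_tamoxifen", tempfile(), kb, seed = 7)
cohort <- generate_cohort(kb, n_per_subtype = 15, seed = 303,
                          with_activities = FALSE)

report <- run_pipeline(
  list(clinical = gen$paths$clinical, expression = gen$paths$expression,
       somatic_vcf = gen$paths$somatic_vcf,
       germline_vcf = gen$paths$germline_vcf,
       seg = gen$paths$seg, methylation = gen$paths$methylation,
       n_perm = 1000, seed = 42, exome_mb = gen$manifest$exome_mb),
  cohort = cohort)

head(glance(report$drug_assessments)[, c("drug_id", "verdict",
                                         "n_supporting", "n_contra")], 6)
#> # A tibble: 6 × 4
#>   drug_id     verdict         n_supporting n_contra
#>   <chr>       <chr>                  <int>    <int>
#> 1 tamoxifen   contraindicated            2        4
#> 2 anastrozole conditional                1        1
#> 3 exemestane  conditional                1        1
#> 4 letrozole   conditional                1        1
#> 5 fulvestrant suggested                  2        0
#> 6 trastuzumab contraindicated            2        2
```

Tamoxifen is contraindicated despite the favorable receptor status: the
fired evidence items name the CYP2D6 frameshift (poor-metabolizer
phenotype blocks activation to endoxifen), the ESR2 frameshift in a drug
target, APOBEC3B overexpression and the high MAPK pathway label. The
aromatase inhibitors come back *conditional* — supported by ER status but
soft-contraindicated by the premenopausal status (ovarian-suppression
note). The PARP inhibitors are *suggested*, citing the BRCA1/2 variants
and PARP1 upregulation.

```r
tidy(report$pathway_activities) |>
  dplyr::filter(pathway_id == "MAPK_signaling")
#>   pathway_id     activity  p_value p_adjusted label n_genes_used
#> 1 MAPK_signaling    0.999 0.000999     0.0200 high            12

head(tibble::as_tibble(report$drivers)[, 1:4], 3)
#> # A tibble: 3 × 4
#>   gene_id channels                severity_grade priority_score
#> 1 BRCA1   mutation                severe                    7.5
#> 2 BRCA2   mutation                severe                    7.5
#> 3 ERBB2   mutation+cna+expression moderate                  4.5

report$consistency_warnings
#> [1] "HER2 clinically negative but ERBB2 strongly overexpressed (score 11.18)"
#> [2] "HER2 clinically negative but ERBB2 amplified (log-ratio 0.59)"
```

The activity 0.999 is the position of the MAPK weighted sum within its
1000-permutation null (hence `p ≈ 1/1001`, adjusted 0.02 across 20
pathways); the consistency check flags that the clinically HER2-negative
sample shows ERBB2 amplification and overexpression. `write_report()`
serializes the whole report to JSON; `export_radar()`,
`export_sunburst()`, `export_tmb_plot_data()` and `export_embedding()`
emit plot-ready data, and `autoplot()` methods draw the radar and
embedding directly.

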