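---
title: "Methods: multi-omics treatment stratification with molboard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics treatment stratification with molboard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molboard)
```

molboard is a headless decision-support backend for a single breast tumor
sample. This vignette is the package's account of its methods: the models
and rules it applies, the tunable parameters and their defaults, the
numerical choices behind the implementation, what the synthetic data
generator does and does not emulate, and the known limitations.

## Input harmonization and deregulation scores

Five input channels are supported: clinical markers (YAML/TSV), gene
expression (TSV, one tumor column plus controls), mutations (VCF 4.x with
VeP-style `CSQ` or snpEff-style `ANN` consequence annotations, or a side
table of per-gene annotations), copy-number segments (SEG log2 ratios) and
promoter methylation (whitespace table of beta values or precomputed
scores). All channels are re-keyed to HGNC symbols through a bundled
cross-reference; the namespace of the incoming identifiers (Ensembl,
Entrez, UniProt, symbol) is detected by regex majority vote, a minority
share above 20% is rejected as ambiguous, and identifiers without a
cross-reference entry are preserved under an `unmapped:` prefix so the
mapping is total and idempotent.

Differential expression is summarized per gene as a *deregulation score*:

* one control sample: `log2((tumor + c) / (control + c))` with pseudocount
  `c = 1` (configurable; a stabilizer for count-like values — use a small
  `c` for beta-scaled data, the methylation path defaults to 0.01);
* two or more controls: `z = (tumor − mean(controls)) / sd(controls)` with
  the sample (n−1) standard deviation. Genes whose controls have zero
  spread get score 0 and a flag instead of an infinity.

Duplicate gene rows collapse by their mean — deterministic and order
independent. Note that z-scores against few controls are heavy-tailed
(t-distributed); with a well-sized control set the score distribution under
exchangeability approaches standard normal, which the test suite checks by
a Kolmogorov–Smirnov test at 30 controls per gene.

## Pathway activities

The activity of each of the 20 bundled cancer-relevant pathways is
approximated by a weighted sum of the deregulation scores of its member
genes; the default bundle weights members +1 (activator) or −1
(inhibitor). Members without a score are skipped and counted; a pathway
with fewer than 25% of its members scored is declared *not assessable*
rather than scored from a sliver of evidence.

Significance and normalization both come from one permutation null: the
gene-to-score assignment is permuted over **all** scored genes (not just
pathway-annotated ones), and the weighted sum is recomputed `n_perm` times
(default 1000, configurable; seed default 42). From this null we report:

* a two-sided empirical P-value with the add-one correction,
  `p = (1 + #{|null| ≥ |observed|}) / (n_perm + 1)`, so `p ∈ (0, 1]` and a
  pathway can be significantly *inactive* as well as active;
* a normalized activity in [0, 1]: the midrank of the observed score
  within the pooled set (null scores plus the observation) divided by the
  pool size plus one. This empirical-CDF position is rank-based and
  scale-free — doubling every deregulation score leaves activities and
  P-values unchanged — and evaluates to exactly 0.5 when there is no
  deregulation signal. Ties take midranks throughout.

P-values are adjusted across pathways by Benjamini–Hochberg (step-up,
clipped at 1; delegated to `stats::p.adjust` behind `adjust_bh()`, with an
independent textbook implementation as the test oracle). Activities map to
qualitative labels: *medium* on the closed interval [0.4, 0.6], *high* on
(0.6, 1], *low* below 0.4.

An exhaustive mode enumerates every ordered assignment instead of sampling
(`empirical_pvalue(..., exhaustive = TRUE)`); it is feasible only for tiny
pools and exists so the sampled estimator can be validated against full
enumeration.

Similarity between the sample and reference samples is the mean squared
difference of corresponding pathway activities, ranked ascending with
lexicographic tie-breaks; pathways not assessable in the query are dropped
pairwise.

## Intrinsic subtype

The sample is embedded with a labeled reference cohort by PCA and t-SNE on
a shared gene panel: genes are intersected, zero-variance genes dropped,
the panel reduced to the top 2000 genes by cohort variance (configurable),
and every gene standardized by the *cohort* mean and standard deviation so
the query cannot shift the reference frame. A query overlapping less than
half of the cohort panel is rejected. PCA signs follow the
largest-loading-positive convention; t-SNE (exact, via Rtsne) is seeded,
initialized from the PCA plane, with perplexity 30 reduced to `(n − 1)/3`
for small cohorts.

Because the reference visualization alone does not yield a testable call,
the package adds an explicit classifier: the subtype call is the majority
label among the k = 15 nearest cohort samples by Euclidean distance in the
standardized full-panel space (never the 2D embedding), with ties broken
toward the subtype with the smaller mean distance. Vote fractions are
reported alongside the call.

## Driver events

Mutations are graded from their VeP-style annotations: *severe* for HIGH
impact (stop gain, frameshift, splice site), *damaging* for MODERATE
impact with SIFT < 0.05 or PolyPhen > 0.85 (the tools' published
conventions; the annotations name the scores but no cutoffs travel with
them), *moderate* for remaining MODERATE impact, *low* for LOW impact,
*unknown* otherwise.

Copy-number segments map to genes as the length-weighted mean of
overlapping segment log-ratios (closed-interval base counts via IRanges;
overlapping input segments resolve to a per-base weighted mean with a
warning). Calls use log-ratio thresholds ±0.3, a common convention for
segmented log2 ratios, configurable.

A catalog gene becomes a *driver event* when at least one channel is
altered: a mutation graded at least moderate, a non-neutral copy-number
call, |methylation score| ≥ 1, or |deregulation| ≥ 2. The priority score —
an explicit, documented surrogate, since prioritization is presented
qualitatively in the source material — is
`catalog weight × severity points (severe 3 / damaging 2 / moderate 1)`
plus one point per additional altered channel, sorted descending with ties
broken by gene id. Driver discovery is deliberately catalog-gated
(lookup-style, no de novo statistics).

## Drug rules and verdicts

The knowledge bundle carries 17 standard-of-care and 23 driver-targeting
(off-label candidate) drugs, each with declarative rule items over a
closed predicate vocabulary: clinical status comparisons, deregulation
thresholds (defaults: z ≥ 2 or log2 FC ≥ 1 for "highly expressed",
mirrored for "low"), loss-of-function presence (any mutation graded
severe), any-mutation presence/absence, a maximum tolerated target
mutation grade, pathway label membership, and copy-number thresholds. A
rule whose subject cannot be resolved in the data is reported as not
assessable rather than silently false.

Per drug, fired items aggregate to a verdict: *contraindicated* when a
decisive contraindication fires (kinds biomarker or metabolizing enzyme —
the gatekeeper factors, e.g. ER status for endocrine therapy or CYP2D6 for
prodrug activation) or at least two contraindications fire overall;
*suggested* when at least one support fires and nothing against;
*conditional* when evidence points both ways below the contraindicated
bar; *not assessable* when nothing could be evaluated. Rule items may be
marked `soft`: a soft decisive contraindication (premenopausal status for
aromatase inhibitors, addressable by ovarian suppression) downgrades to
*conditional* instead of ruling the drug out. Clinical-vs-omics
consistency checks (e.g. HER2-negative status against ERBB2 amplification
or strong overexpression) use the same thresholds and attach warnings to
the assessment rather than changing verdicts.

The bundled rule tables are a curated synthetic stand-in with the correct
cardinalities; entries discussed in the accompanying case material are
flagged `paper_named`, the rest are plausible placeholder curations. The
YAML schema makes the bundle replaceable by a faithful curation.

## Immunotherapy section

Tumor mutational burden is the number of distinct somatic variants per
megabase of exonic territory. `exome_mb` is an explicit required parameter
(default 30 for a human exome; the synthetic cases use the toy genome's
3.3 Mb), because the divisor is a property of the capture design, not of
the variant file. When exon intervals are supplied the count is restricted
to them, otherwise all somatic variants count and the report flags it.
Duplicate variants count once. The cohort percentile is the midrank of the
observed TMB within the pooled cohort-plus-observation set, scaled to
0–100 — monotone in TMB and well-defined under ties; its floor is
`100·0.5/(n+1)` rather than exactly 0.

Repair genes are *impaired* when their best mutation grade is severe or
damaging; the checkpoint-biomarker overview tabulates deregulation,
copy-number, methylation and mutation grade per gene. Neoepitope
prediction and HLA typing are external steps; the report reserves a note
instead of emulating them.

## Synthetic data

`generate_cohort()` emulates an intrinsic-subtype expression cohort:
per-subtype centroids at baseline log2 expression 8 over the 330-gene
knowledge universe, with marker blocks shifted by 1.5–4 log2 units
(hormone-receptor block in luminal tumors, ERBB2 block in HER2-enriched,
focal-adhesion/HIF-1/MAPK blocks plus receptor loss in basal-like,
proliferation separating luminal B from A) and i.i.d. Gaussian noise
(default sd 1). Cohort pathway activities and TMB values are computed
through the real pipeline for self-consistency. Defaults: 30 samples per
subtype, 200 permutations for the cohort activity matrix.

`generate_case()` writes complete input file sets with planted
alterations for three scenarios — a pathway-driven ER−/PR+ tumor with an
inactive PI3K-Akt axis, a tamoxifen-resistance case (CYP2D6/ESR2
frameshifts, APOBEC3B/ERBB2/PARP1 upregulation, BRCA1/2 germline
variants, high MAPK activity), and a hypermutated triple-negative case
(≈150 somatic variants on the 3.3 Mb toy genome with disabled
TP53/RB1/ATM/MLH1) — plus a manifest of every plant. The toy genome is 10
chromosomes × 33 genes (10 kb bodies, 5 kb gaps). Expression plants shift
the tumor by ±4 log2 units over controls with sd 0.5, which keeps planted
z-scores above the rule-engine thresholds with overwhelming probability
at any seed.

What the generator does **not** emulate: mutational signatures and
transition/transversion structure, linkage and copy-number coherence along
real chromosomes, probe-level methylation, batch and platform effects, and
realistic correlation between channels. Passing tests on this material
therefore demonstrate the correctness of the computations and rules, not
classifier performance on real tumors.

## Numerical choices and problem sizes

Tie handling is midrank everywhere ranks appear. Degenerate inputs are
handled explicitly: zero-spread controls flag instead of dividing by zero,
empty channels mark downstream stages skipped or not assessable, and a
pathway covering the whole score pool yields p = 1 by exchangeability.
Seeds: every stochastic stage (permutation null, t-SNE, generators) takes
an explicit seed; reports record the run parameters.

The test suite runs the permutation-calibration check at 200 null pathways
× 500 permutations, subtype recovery on a 120-sample training cohort with
40 held-out samples, and the case studies at 500 permutations — sizes
chosen so the whole suite completes in well under a minute per file while
keeping the statistical checks meaningful.

## Limitations

The pathway activity normalization is a rank-based surrogate on the
published [0, 1] scale; absolute activity values from other
implementations of the same idea need not match, although labels and
significance calls are comparable. The drug knowledge is a structured
fixture, not a clinical rulebook. CYP2D6 loss is inferred from consequence
class only (no star-allele diplotyping), clonality, phasing and liftover
are out of scope, and nothing in the output is a treatment recommendation.
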