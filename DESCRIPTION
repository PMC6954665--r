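Package: molboard
Title: Multi-Omics Treatment Stratification for Breast Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless molecular-tumor-board analytics for a single breast
    tumor sample. Integrates clinical markers with expression, mutation,
    copy-number and promoter-methylation data; computes per-gene
    deregulation scores, driver-event prioritization, activity scores for
    20 core cancer-relevant pathways with permutation P-values and
    Benjamini-Hochberg adjustment, intrinsic-subtype embedding and calling
    against a reference cohort, tumor mutational burden with cohort
    percentile, and a rule-based assessment of standard-of-care and
    off-label (driver-targeting) drugs. Emits an auditable JSON report and
    visualization-ready data exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    S4Vectors,
    graphics,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
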