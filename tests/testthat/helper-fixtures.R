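# Shared fixtures: the bundled knowledge base is loaded once per session,
# and small omics bundles are built in code.

.fixture_env <- new.env(parent = emptyenv())

test_kb <- function() {
  if (is.null(.fixture_env$kb)) .fixture_env$kb <- load_knowledge_base()
  .fixture_env$kb
}

# deregulation tibble from a named numeric vector
make_dereg <- function(scores, kind = "z_score") {
  tibble::tibble(gene_id = names(scores), score = unname(scores),
                 score_kind = kind, flagged = FALSE)
}

# mutation tibble builder with sensible defaults
make_mutations <- function(gene_id, consequence, origin = "somatic",
                           sift = NA_real_, polyphen = NA_real_,
                           impact = NULL, chrom = "chr1", pos = NULL) {
  n <- length(gene_id)
  cons <- rep_len(consequence, n)
  tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) seq(1000L, by = 100L, length.out = n) else pos,
    ref = "A", alt = "T",
    origin = rep_len(origin, n), gene_id = gene_id,
    consequence = cons,
    impact = if (is.null(impact)) molboard:::impact_for_consequence(cons)
             else rep_len(impact, n),
    sift = rep_len(sift, n), polyphen = rep_len(polyphen, n)
  )
}

make_clinical <- function(...) {
  clinical_record(patient_id = "TEST01", ...)
}

# case-2-like bundle assembled directly (no file round trip)
make_case2_bundle <- function() {
  dereg <- make_dereg(c(ESR1 = 2.5, APOBEC3B = 3.1, PARP1 = 4.9,
                        ERBB2 = 4.0, PGR = 1.0, GENE0001 = 0.1,
                        VEGFA = 0.0, ABCB1 = -0.5))
  muts <- dplyr::bind_rows(
    make_mutations("CYP2D6", "frameshift_variant", origin = "germline"),
    make_mutations("ESR2", "frameshift_variant", origin = "somatic"),
    make_mutations("BRCA1", "frameshift_variant", origin = "germline"),
    make_mutations("BRCA2", "stop_gained", origin = "germline"),
    make_mutations("ERBB2", "missense_variant", origin = "somatic",
                   sift = 0.4, polyphen = 0.3)
  )
  assemble_bundle(
    clinical = make_clinical(er_status = "positive", pr_status = "positive",
                             her2_status = "negative",
                             menopausal_status = "pre"),
    deregulation = dereg, mutations = muts,
    cna = tibble::tibble(gene_id = "ERBB2", log_ratio = 0.8,
                         call = "amplified")
  )
}

# pathway activities stub with a chosen label for one pathway
make_activities <- function(pathway_id = "MAPK_signaling", label = "high") {
  tibble::tibble(pathway_id = pathway_id, raw_score = 10, activity = 0.99,
                 p_value = 0.001, p_adjusted = 0.02, label = label,
                 n_genes_used = 10L, n_members = 12L,
                 n_permutations = 1000L, assessable = TRUE)
}
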