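# Subtype centroid shifts (log2 expression units) over the knowledge genes.
# Marker blocks follow the intrinsic-subtype biology the classifier relies
# on: hormone-receptor block in luminal tumors, ERBB2 block in
# HER2-enriched, basal/stem-pathway blocks (focal adhesion, HIF-1, MAPK)
# plus receptor loss in basal-like, proliferation block separating
# luminal B from luminal A.
subtype_centroid_shifts <- function() {
  hr <- c("ESR1", "ESR2", "PGR", "GREB1", "TFF1", "FOXA1", "GATA3")
  prolif <- c("MKI67", "AURKA", "PLK1", "CCNE1", "E2F1", "CDK2")
  her2 <- c("ERBB2", "ERBB3", "GRB2")
  basal <- c("PTK2", "SRC", "ITGB1", "ITGA5", "FN1", "HIF1A", "SLC2A1",
             "LDHA", "VEGFA", "KDR")
  mapk <- c("BRAF", "KRAS", "NRAS", "MAPK1", "MAPK3")
  list(
    "luminal A" = c(setNames(rep(3, length(hr)), hr),
                    setNames(rep(-1, length(prolif)), prolif)),
    "luminal B" = c(setNames(rep(2.5, length(hr)), hr),
                    setNames(rep(2, length(prolif)), prolif)),
    "HER2-enriched" = c(setNames(rep(4, length(her2)), her2),
                        setNames(rep(-2, length(hr)), hr),
                        setNames(rep(1.5, length(prolif)), prolif)),
    "basal-like" = c(setNames(rep(-2.5, length(hr)), hr),
                     setNames(rep(-2, length(her2)), her2),
                     setNames(rep(2.5, length(basal)), basal),
                     setNames(rep(1.5, length(mapk)), mapk),
                     setNames(rep(2, length(prolif)), prolif))
  )
}

#' Generate a labeled synthetic reference cohort
#'
#' Emulates an expression reference cohort of the four intrinsic breast
#' cancer subtypes: per-subtype centroids over the knowledge-base gene
#' universe (baseline log2 expression 8) with marker blocks shifted as in
#' [subtype_centroid_shifts()], plus i.i.d. Gaussian noise. Cohort pathway
#' activities are computed through the real scoring pipeline
#' (per-sample z-scores against the cohort itself), and cohort TMB values
#' through [compute_tmb()] on generated somatic variant sets, so the
#' cohort is self-consistent with the analysis stages.
#'
#' @param kb `knowledge_base`.
#' @param n_per_subtype Samples per subtype (default 30).
#' @param noise_sd Gaussian noise standard deviation in log2 units
#'   (default 1).
#' @param seed Seed (default 1); the cohort is reproducible from
#'   `(spec, seed)`.
#' @param n_perm Permutations per pathway for the cohort activity matrix
#'   (default 200).
#' @param exome_mb Exonic territory of the toy genome in megabases
#'   (default 3.3).
#' @param with_activities Compute the pathway-activity matrix (default
#'   TRUE; the slowest part).
#' @return `reference_cohort` with `expression`, `labels`, `activities`
#'   (tibble `sample_id` + one column per pathway) and `tmb`.
#' @export
generate_cohort <- function(kb, n_per_subtype = 30, noise_sd = 1, seed = 1,
                            n_perm = 200, exome_mb = 3.3,
                            with_activities = TRUE) {
  set.seed(seed)
  genes <- kb$xref$symbol
  shifts <- subtype_centroid_shifts()
  baseline <- 8
  samples <- list()
  labels <- character(0)
  for (st in SUBTYPES) {
    centroid <- rep(baseline, length(genes))
    names(centroid) <- genes
    sh <- shifts[[st]]
    sh <- sh[names(sh) %in% genes]
    centroid[names(sh)] <- centroid[names(sh)] + sh
    for (i in seq_len(n_per_subtype)) {
      sid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", st), i)
      samples[[sid]] <- centroid + rnorm(length(genes), 0, noise_sd)
      labels[sid] <- st
    }
  }
  expr <- do.call(rbind, samples)
  colnames(expr) <- genes

  activities <- NULL
  if (with_activities) {
    mu <- colMeans(expr)
    s <- apply(expr, 2, sd)
    s[s == 0] <- 1
    act_rows <- purrr::imap(samples, function(x, sid) {
      dereg <- tibble(gene_id = genes, score = (x - mu) / s,
                      score_kind = "z_score", flagged = FALSE)
      pa <- score_pathways(dereg, kb, n_perm = n_perm,
                           seed = sample.int(2^30, 1))
      setNames(as.list(pa$activity), pa$pathway_id)
    })
    activities <- dplyr::bind_rows(act_rows) %>%
      mutate(sample_id = names(samples)) %>%
      select(sample_id, dplyr::everything())
  }

  gm <- kb$gene_models
  tmb <- vapply(names(samples), function(sid) {
    n_mut <- max(1L, round(stats::rlnorm(1, meanlog = log(30), sdlog = 0.8)))
    rows <- sample.int(nrow(gm), n_mut, replace = TRUE)
    muts <- tibble(
      chrom = gm$chrom[rows],
      pos = as.integer(gm$start[rows] +
                         floor(runif(n_mut) * (gm$end[rows] - gm$start[rows]))),
      ref = "A", alt = "T", origin = "somatic",
      gene_id = gm$gene_id[rows], consequence = "other",
      impact = "MODIFIER", sift = NA_real_, polyphen = NA_real_
    ) %>% distinct(chrom, pos, .keep_all = TRUE)
    compute_tmb(muts, exome_mb = exome_mb)$tmb
  }, numeric(1))

  reference_cohort(expr, labels, activities = activities, tmb = tmb)
}

# planted alteration tables per case template ------------------------------

case_plants <- function(template) {
  switch(template,
    case1_pathway = list(
      clinical = list(er_status = "negative", pr_status = "positive",
                      her2_status = "negative", menopausal_status = "post",
                      grade = 3L, tnm_t = "T3", tnm_n = "N1", tnm_m = "M0"),
      expr_up = c("BRAF", "KRAS", "NRAS", "MAPK1", "MAPK3", "VEGFA", "KDR",
                  "PTK2", "SRC", "ITGB1", "FN1", "HIF1A", "SLC2A1", "LDHA"),
      expr_down = c("PIK3CA", "PIK3R1", "AKT1", "AKT2", "MTOR", "PDPK1",
                    "RPS6KB1", "GSK3B"),
      somatic = tibble(gene_id = character(), consequence = character(),
                       sift = double(), polyphen = double()),
      germline = tibble(gene_id = character(), consequence = character(),
                        sift = double(), polyphen = double()),
      amplified = character(0), deleted = character(0),
      hypermethylated = character(0), n_passenger_somatic = 15L
    ),
    case2_tamoxifen = list(
      clinical = list(er_status = "positive", pr_status = "positive",
                      her2_status = "negative", menopausal_status = "pre",
                      grade = 2L, tnm_t = "T2", tnm_n = "N0", tnm_m = "M0"),
      expr_up = c("APOBEC3B", "PARP1", "ERBB2", "ESR1",
                  "BRAF", "KRAS", "NRAS", "MAPK1", "MAPK3", "RAF1",
                  "MAP2K1", "MAP2K2", "EGFR"),
      expr_down = character(0),
      somatic = tibble(
        gene_id = c("ESR2", "ERBB2"),
        consequence = c("frameshift_variant", "missense_variant"),
        sift = c(NA, 0.35), polyphen = c(NA, 0.4)),
      germline = tibble(
        gene_id = c("CYP2D6", "BRCA1", "BRCA2"),
        consequence = c("frameshift_variant", "frameshift_variant",
                        "stop_gained"),
        sift = c(NA, NA, NA), polyphen = c(NA, NA, NA)),
      amplified = "ERBB2", deleted = character(0),
      hypermethylated = character(0), n_passenger_somatic = 12L
    ),
    case3_immuno = list(
      clinical = list(er_status = "negative", pr_status = "negative",
                      her2_status = "negative", menopausal_status = "post",
                      grade = 3L, tnm_t = "T4", tnm_n = "N2", tnm_m = "M1",
                      sample_origin = "metastasis"),
      expr_up = c("CD274", "PDCD1", "MKI67", "AURKA", "PTK2", "SRC",
                  "ITGB1", "FN1", "HIF1A", "SLC2A1", "LDHA"),
      expr_down = c("ESR1", "PGR", "ERBB2"),
      somatic = tibble(
        gene_id = c("TP53", "RB1", "ATM", "MLH1"),
        consequence = c("stop_gained", "frameshift_variant",
                        "missense_variant", "frameshift_variant"),
        sift = c(NA, NA, 0.01, NA), polyphen = c(NA, NA, 0.97, NA)),
      germline = tibble(gene_id = "CHEK2", consequence = "missense_variant",
                        sift = 0.3, polyphen = 0.2),
      amplified = character(0), deleted = c("RB1", "TP53"),
      hypermethylated = "MLH1", n_passenger_somatic = 150L
    ),
    random = list(
      clinical = list(er_status = "positive", pr_status = "unknown",
                      her2_status = "negative", menopausal_status = "post"),
      expr_up = character(0), expr_down = character(0),
      somatic = tibble(gene_id = character(), consequence = character(),
                       sift = double(), polyphen = double()),
      germline = tibble(gene_id = character(), consequence = character(),
                        sift = double(), polyphen = double()),
      amplified = character(0), deleted = character(0),
      hypermethylated = character(0), n_passenger_somatic = 20L
    ),
    abort_input(paste("unknown case template:", template))
  )
}

random_position_in <- function(gm, gene) {
  j <- match(gene, gm$gene_id)
  if (is.na(j)) abort_internal(paste("gene not in toy gene models:", gene))
  list(chrom = gm$chrom[j],
       pos = as.integer(gm$start[j] + floor(runif(1) * (gm$end[j] - gm$start[j]))))
}

plant_mutations <- function(plants_tbl, gm, origin) {
  if (nrow(plants_tbl) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), origin = character(),
                  gene_id = character(), consequence = character(),
                  impact = character(), sift = double(),
                  polyphen = double()))
  }
  purrr::map_dfr(seq_len(nrow(plants_tbl)), function(i) {
    loc <- random_position_in(gm, plants_tbl$gene_id[i])
    cons <- plants_tbl$consequence[i]
    tibble(chrom = loc$chrom, pos = loc$pos,
           ref = sample(c("A", "C", "G", "T"), 1), alt = "T",
           origin = origin, gene_id = plants_tbl$gene_id[i],
           consequence = cons, impact = impact_for_consequence(cons),
           sift = plants_tbl$sift[i], polyphen = plants_tbl$polyphen[i])
  }) %>%
    mutate(alt = ifelse(alt == ref, "G", alt))
}

passenger_mutations <- function(n, gm, origin = "somatic") {
  if (n == 0) return(plant_mutations(tibble(gene_id = character(),
                                            consequence = character(),
                                            sift = double(),
                                            polyphen = double()), gm, origin))
  rows <- sample.int(nrow(gm), n, replace = TRUE)
  cons <- sample(c("synonymous_variant", "missense_variant", "other"), n,
                 replace = TRUE, prob = c(0.4, 0.35, 0.25))
  tbl <- tibble(gene_id = gm$gene_id[rows], consequence = cons,
                sift = ifelse(cons == "missense_variant",
                              round(runif(n, 0.1, 1), 3), NA_real_),
                polyphen = ifelse(cons == "missense_variant",
                                  round(runif(n, 0, 0.8), 3), NA_real_))
  plant_mutations(tbl, gm, origin) %>%
    distinct(chrom, pos, .keep_all = TRUE)
}

#' Generate a complete synthetic case-study input set
#'
#' Writes the full file set one pipeline run consumes — clinical YAML,
#' expression TSV (tumor + 3 controls), somatic and germline VCFs with
#' VeP-style CSQ annotations, SEG copy-number segments and a methylation
#' beta table — with the planted alterations of the chosen template, plus
#' a manifest JSON listing every plant for downstream assertions.
#'
#' Templates: `case1_pathway` (ER-/PR+/HER2- tumor with MAPK, focal
#' adhesion and HIF-1 upregulation and an inactive PI3K-Akt axis),
#' `case2_tamoxifen` (HR+/HER2- premenopausal tumor with CYP2D6 and ESR2
#' frameshifts, APOBEC3B/ERBB2/PARP1 upregulation, BRCA1/2 germline
#' variants and high MAPK activity), `case3_immuno` (triple-negative
#' metastatic tumor with high mutational burden and disabled TP53 / RB1 /
#' ATM / MLH1), `random` (background alterations only).
#'
#' @param template Case template id.
#' @param dir Output directory (created if needed).
#' @param kb `knowledge_base`.
#' @param seed Seed making the file set reproducible.
#' @param exome_mb Toy-genome exonic territory recorded in the manifest
#'   (default 3.3).
#' @return Invisible list with file `paths` and the `manifest`.
#' @export
generate_case <- function(template, dir, kb, seed = 1, exome_mb = 3.3) {
  plants <- case_plants(template)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- kb$gene_models
  genes <- kb$xref$symbol

  # clinical ---------------------------------------------------------------
  clinical <- c(list(patient_id = sprintf("%s_seed%d", template, seed)),
                plants$clinical)
  clinical_path <- file.path(dir, "clinical.yaml")
  yaml::write_yaml(clinical, clinical_path)

  # expression: controls around a shared baseline, tumor shifted by plants
  base <- rnorm(length(genes), 8, 0.5)
  delta <- setNames(rep(0, length(genes)), genes)
  delta[plants$expr_up] <- 4
  delta[plants$expr_down] <- -4
  ctrl <- vapply(1:3, function(i) base + rnorm(length(genes), 0, 0.5),
                 numeric(length(genes)))
  tumor <- base + delta + rnorm(length(genes), 0, 0.5)
  expr_path <- file.path(dir, "expression.tsv")
  write_expression(
    tibble(gene_id = genes, tumor_value = tumor,
           control_values = purrr::array_branch(ctrl, 1)),
    expr_path)

  # mutations --------------------------------------------------------------
  somatic <- dplyr::bind_rows(
    plant_mutations(plants$somatic, gm, "somatic"),
    passenger_mutations(plants$n_passenger_somatic, gm, "somatic")
  ) %>% distinct(chrom, pos, .keep_all = TRUE) %>% arrange(chrom, pos)
  germline <- plant_mutations(plants$germline, gm, "germline") %>%
    arrange(chrom, pos)
  somatic_path <- file.path(dir, "somatic.vcf")
  germline_path <- file.path(dir, "germline.vcf")
  write_vcf(somatic, somatic_path)
  write_vcf(germline, germline_path)

  # copy number: 3 segments per chromosome, planted amp/del over genes
  seg <- purrr::map_dfr(unique(gm$chrom), function(chr) {
    g <- gm[gm$chrom == chr, ]
    span <- max(g$end) + 2000
    cuts <- sort(sample(2000:(span - 2000), 2))
    tibble(chrom = chr, start = c(1L, cuts + 1L),
           end = c(cuts, span), log_ratio = round(rnorm(3, 0, 0.1), 3))
  })
  for (g in plants$amplified) {
    j <- match(g, gm$gene_id)
    seg <- dplyr::bind_rows(seg, tibble(chrom = gm$chrom[j],
                                        start = gm$start[j] - 500L,
                                        end = gm$end[j] + 500L,
                                        log_ratio = 1.2))
  }
  for (g in plants$deleted) {
    j <- match(g, gm$gene_id)
    seg <- dplyr::bind_rows(seg, tibble(chrom = gm$chrom[j],
                                        start = gm$start[j] - 500L,
                                        end = gm$end[j] + 500L,
                                        log_ratio = -1.2))
  }
  seg_path <- file.path(dir, "cna.seg")
  readr::write_tsv(
    tibble(sample = clinical$patient_id, chrom = seg$chrom,
           start = seg$start, end = seg$end, num_mark = 50L,
           seg_mean = seg$log_ratio),
    seg_path, progress = FALSE)

  # methylation: background betas, planted promoter hypermethylation
  beta_base <- runif(length(genes), 0.2, 0.6)
  beta_base[match(plants$hypermethylated, genes)] <- 0.2
  tumor_beta <- pmin(0.99, pmax(0.01, beta_base + rnorm(length(genes), 0, 0.03)))
  ctrl_beta <- pmin(0.99, pmax(0.01, beta_base + rnorm(length(genes), 0, 0.03)))
  hyper <- match(plants$hypermethylated, genes)
  tumor_beta[hyper] <- 0.95
  meth_path <- file.path(dir, "methylation.tsv")
  meth_tbl <- data.frame(gene_id = genes, tumor = round(tumor_beta, 4),
                         control_1 = round(ctrl_beta, 4))
  utils::write.table(meth_tbl, meth_path, sep = " ", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    template = template, seed = seed, exome_mb = exome_mb,
    n_somatic_written = nrow(somatic), n_germline_written = nrow(germline),
    plants = list(
      expression_up = plants$expr_up, expression_down = plants$expr_down,
      somatic = plants$somatic$gene_id, germline = plants$germline$gene_id,
      amplified = plants$amplified, deleted = plants$deleted,
      hypermethylated = plants$hypermethylated
    ),
    files = list(clinical = "clinical.yaml", expression = "expression.tsv",
                 somatic_vcf = "somatic.vcf", germline_vcf = "germline.vcf",
                 seg = "cna.seg", methylation = "methylation.tsv")
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    paths = list(dir = dir, clinical = clinical_path, expression = expr_path,
                 somatic_vcf = somatic_path, germline_vcf = germline_path,
                 seg = seg_path, methylation = meth_path,
                 manifest = manifest_path),
    manifest = manifest
  ))
}
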