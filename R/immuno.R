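#' Tumor mutational burden
#'
#' TMB is the number of somatic mutations per megabase of exonic territory.
#' Duplicate variants (same chrom/pos/ref/alt) are counted once; when exon
#' intervals are supplied the count is restricted to variants falling
#' inside them, otherwise all somatic variants count (flagged in the
#' result).
#'
#' @param mutations Mutation tibble with `origin` labels.
#' @param exome_mb Exonic territory in megabases (> 0; default 30).
#' @param exon_filter Optional interval tibble (`chrom`, `start`, `end`,
#'   1-based inclusive), e.g. the knowledge-base gene models.
#' @param cohort_tmbs Optional numeric cohort TMB vector for the
#'   percentile.
#' @return One-row tibble of class `tmb_result`: `n_somatic`, `exome_mb`,
#'   `tmb`, `log10_tmb`, `cohort_percentile`, `exon_filtered`.
#' @export
compute_tmb <- function(mutations, exome_mb = 30, exon_filter = NULL,
                        cohort_tmbs = NULL) {
  if (exome_mb <= 0) abort_input("exome_mb must be positive")
  if (is.null(mutations) || !"origin" %in% names(mutations)) {
    abort_input("cannot derive somatic set: mutations lack origin labels")
  }
  if (nrow(mutations) > 0 &&
      !all(mutations$origin %in% c("somatic", "germline"))) {
    abort_input("cannot derive somatic set: origin must be somatic/germline")
  }
  som <- mutations %>%
    filter(origin == "somatic") %>%
    distinct(chrom, pos, ref, alt)
  if (!is.null(exon_filter) && nrow(som) > 0) {
    keep <- map_lgl(seq_len(nrow(som)), function(i) {
      any(exon_filter$chrom == som$chrom[i] &
            exon_filter$start <= som$pos[i] &
            exon_filter$end >= som$pos[i])
    })
    som <- som[keep, ]
  }
  n <- nrow(som)
  tmb <- n / exome_mb
  pct <- if (is.null(cohort_tmbs)) NA_real_ else tmb_percentile(tmb, cohort_tmbs)
  out <- tibble(
    n_somatic = n, exome_mb = exome_mb, tmb = tmb,
    log10_tmb = if (tmb > 0) log10(tmb) else NA_real_,
    cohort_percentile = pct,
    exon_filtered = !is.null(exon_filter)
  )
  class(out) <- c("tmb_result", class(out))
  out
}

#' Cohort percentile of a TMB value
#'
#' Midrank percentile of the observed TMB within the pooled set of cohort
#' values and the observation:
#' `100 * (#below + 0.5 * (#ties + 1)) / (n_cohort + 1)`.
#'
#' @param tmb Observed TMB.
#' @param cohort_tmbs Numeric cohort vector.
#' @return Percentile in \[0, 100\].
#' @export
tmb_percentile <- function(tmb, cohort_tmbs) {
  if (length(cohort_tmbs) == 0) abort_input("empty cohort TMB vector")
  100 * (sum(cohort_tmbs < tmb) + 0.5 * (sum(cohort_tmbs == tmb) + 1)) /
    (length(cohort_tmbs) + 1)
}

#' DNA-repair gene status
#'
#' Grades every mutation in each repair-list gene and marks the gene
#' impaired when its best (most severe) grade is `severe` or `damaging`.
#'
#' @param bundle `omics_bundle`.
#' @param repair_genes Character vector of repair genes (e.g.
#'   `kb$gene_lists` subset `dna_repair`).
#' @return Tibble `gene_id`, `best_grade`, `impaired`, sorted by gene.
#' @export
repair_gene_status <- function(bundle, repair_genes) {
  if (inherits(repair_genes, "data.frame")) {
    repair_genes <- repair_genes$gene_id
  }
  muts <- bundle$mutations
  purrr::map_dfr(sort(unique(repair_genes)), function(g) {
    grades <- if (!is.null(muts) && nrow(muts) > 0) {
      mg <- muts[!is.na(muts$gene_id) & muts$gene_id == g, ]
      if (nrow(mg) > 0) grade_mutation(mg) else character(0)
    } else character(0)
    best <- if (length(grades) == 0) "unknown" else
      SEVERITY_GRADES[min(match(grades, SEVERITY_GRADES))]
    tibble(gene_id = g, best_grade = best,
           impaired = best %in% c("severe", "damaging"))
  })
}

#' Checkpoint-biomarker overview
#'
#' Per-gene table of the (epi-)genomic and transcriptomic status of
#' checkpoint-inhibitor biomarker genes: deregulation score, copy-number
#' log-ratio and call, differential methylation and best mutation grade.
#'
#' @param bundle `omics_bundle`.
#' @param checkpoint_genes Character vector (or `kb$gene_lists` subset).
#' @return Tibble sorted by `gene_id`.
#' @export
checkpoint_overview <- function(bundle, checkpoint_genes) {
  if (inherits(checkpoint_genes, "data.frame")) {
    checkpoint_genes <- checkpoint_genes$gene_id
  }
  muts <- bundle$mutations
  purrr::map_dfr(sort(unique(checkpoint_genes)), function(g) {
    dereg <- if (!is.null(bundle$deregulation)) {
      j <- match(g, bundle$deregulation$gene_id)
      if (is.na(j)) NA_real_ else bundle$deregulation$score[j]
    } else NA_real_
    lr <- NA_real_; call <- NA_character_
    if (!is.null(bundle$cna) && nrow(bundle$cna) > 0) {
      j <- match(g, bundle$cna$gene_id)
      if (!is.na(j)) {
        lr <- bundle$cna$log_ratio[j]
        call <- bundle$cna$call[j]
      }
    }
    meth <- if (!is.null(bundle$methylation_diff)) {
      j <- match(g, bundle$methylation_diff$gene_id)
      if (is.na(j)) NA_real_ else bundle$methylation_diff$score[j]
    } else NA_real_
    grades <- if (!is.null(muts) && nrow(muts) > 0) {
      mg <- muts[!is.na(muts$gene_id) & muts$gene_id == g, ]
      if (nrow(mg) > 0) grade_mutation(mg) else character(0)
    } else character(0)
    best <- if (length(grades) == 0) "unknown" else
      SEVERITY_GRADES[min(match(grades, SEVERITY_GRADES))]
    tibble(gene_id = g, deregulation_score = dereg, cna_log_ratio = lr,
           cna_call = call, methylation_score = meth, mutation_grade = best)
  })
}

#' Export TMB plot data (cohort histogram + log-scatter)
#'
#' Produces the data behind the cohort TMB visualization: histogram bin
#' counts of cohort TMB values, the sorted per-sample `log10` TMB points,
#' and the query sample's TMB with percentile.
#'
#' @param result `tmb_result` row.
#' @param cohort_tmbs Numeric cohort TMB vector.
#' @param path Optional JSON output path.
#' @param n_bins Histogram bin count (default 20).
#' @return Export list (invisibly when written).
#' @export
export_tmb_plot_data <- function(result, cohort_tmbs, path = NULL,
                                 n_bins = 20) {
  h <- graphics::hist(cohort_tmbs, breaks = n_bins, plot = FALSE)
  sorted <- sort(cohort_tmbs)
  out <- list(
    histogram = list(breaks = h$breaks, counts = h$counts),
    cohort_sorted_log10_tmb = ifelse(sorted > 0, log10(sorted), NA),
    query = list(tmb = result$tmb, log10_tmb = result$log10_tmb,
                 n_somatic = result$n_somatic,
                 cohort_percentile = result$cohort_percentile)
  )
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out)
}
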