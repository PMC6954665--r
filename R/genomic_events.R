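#' Grade mutation severity
#'
#' Combines the VeP-style impact class with SIFT and PolyPhen scores:
#' `severe` for HIGH impact (stop gain, frameshift, splice site), `damaging`
#' for MODERATE impact with SIFT < 0.05 (deleterious) or PolyPhen > 0.85
#' (probably damaging), `moderate` for the remaining MODERATE impact,
#' `low` for LOW impact, `unknown` otherwise.
#'
#' @param mutations Mutation tibble (or a single-row list) with `impact`,
#'   `sift`, `polyphen`.
#' @return Character vector of severity grades, one per mutation.
#' @export
grade_mutation <- function(mutations) {
  impact <- mutations$impact
  sift <- mutations$sift %||% rep(NA_real_, length(impact))
  polyphen <- mutations$polyphen %||% rep(NA_real_, length(impact))
  dplyr::case_when(
    impact == "HIGH" ~ "severe",
    impact == "MODERATE" &
      ((!is.na(sift) & sift < 0.05) |
         (!is.na(polyphen) & polyphen > 0.85)) ~ "damaging",
    impact == "MODERATE" ~ "moderate",
    impact == "LOW" ~ "low",
    TRUE ~ "unknown"
  )
}

#' Assign gene identifiers to mutations by genomic position
#'
#' Fills missing `gene_id` values by overlap with the gene models
#' (half-open interval arithmetic internally).
#'
#' @param mutations Mutation tibble.
#' @param gene_models Tibble `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return Mutation tibble with `gene_id` filled where a model overlaps.
#' @export
assign_mutation_genes <- function(mutations, gene_models) {
  if (nrow(mutations) == 0) return(mutations)
  need <- which(is.na(mutations$gene_id))
  for (i in need) {
    hit <- which(gene_models$chrom == mutations$chrom[i] &
                   gene_models$start <= mutations$pos[i] &
                   gene_models$end >= mutations$pos[i])
    if (length(hit) > 0) mutations$gene_id[i] <- gene_models$gene_id[hit[1]]
  }
  mutations
}

#' Map copy-number segments to gene-level calls
#'
#' Each gene's log-ratio is the length-weighted mean of the segment
#' log-ratios overlapping its model. Overlap base counts are computed with
#' IRanges interval arithmetic on the native 1-based inclusive SEG/model
#' coordinates (equivalent to half-open per-base accumulation).
#' Overlapping input segments contribute
#' a per-base weighted mean with a warning. Genes without any overlap are
#' omitted.
#'
#' @param segments Segment tibble from [read_seg()].
#' @param gene_models Tibble `gene_id`, `chrom`, `start`, `end`.
#' @param amp_threshold Log-ratio at or above which a gene is `amplified`
#'   (default 0.3).
#' @param del_threshold Log-ratio at or below which a gene is `deleted`
#'   (default -0.3).
#' @return Tibble `gene_id`, `log_ratio`, `call`.
#' @export
map_segments_to_genes <- function(segments, gene_models,
                                  amp_threshold = 0.3,
                                  del_threshold = -0.3) {
  if (nrow(segments) == 0) {
    return(tibble(gene_id = character(), log_ratio = double(),
                  call = character()))
  }
  # overlap among input segments?
  by_chr <- split(segments, segments$chrom)
  has_overlap <- any(map_lgl(by_chr, function(s) {
    ir <- IRanges::IRanges(start = s$start, end = s$end)
    any(IRanges::countOverlaps(ir, ir) > 1)
  }))
  if (has_overlap) {
    warn_molboard(
      "overlapping SEG segments resolved by per-base weighted mean")
  }
  out <- purrr::map_dfr(unique(gene_models$chrom), function(chr) {
    gm <- gene_models[gene_models$chrom == chr, ]
    sg <- segments[segments$chrom == chr, ]
    if (nrow(sg) == 0 || nrow(gm) == 0) return(NULL)
    gir <- IRanges::IRanges(start = gm$start, end = gm$end)
    sir <- IRanges::IRanges(start = sg$start, end = sg$end)
    ov <- IRanges::findOverlaps(gir, sir)
    if (length(ov) == 0) return(NULL)
    hits <- tibble(
      gene_id = gm$gene_id[S4Vectors::queryHits(ov)],
      w = IRanges::width(IRanges::pintersect(
        gir[S4Vectors::queryHits(ov)], sir[S4Vectors::subjectHits(ov)])),
      log_ratio = sg$log_ratio[S4Vectors::subjectHits(ov)]
    )
    hits %>%
      group_by(gene_id) %>%
      summarise(log_ratio = sum(w * log_ratio) / sum(w), .groups = "drop")
  })
  out %>%
    mutate(call = dplyr::case_when(
      log_ratio >= amp_threshold ~ "amplified",
      log_ratio <= del_threshold ~ "deleted",
      TRUE ~ "neutral"
    )) %>%
    arrange(gene_id)
}

# severity points used by the driver priority score
severity_points <- function(grade) {
  dplyr::case_when(
    grade == "severe" ~ 3,
    grade == "damaging" ~ 2,
    grade == "moderate" ~ 1,
    TRUE ~ 0
  )
}

#' Prioritize putative driver events
#'
#' A catalog gene becomes a driver event when at least one channel is
#' altered: a mutation graded at least `moderate`, a non-neutral
#' copy-number call, an absolute differential-methylation score at or above
#' `methylation_threshold`, or an absolute deregulation score at or above
#' `expression_threshold`. The priority score is
#' `catalog weight x severity points (severe 3 / damaging 2 / moderate 1)`
#' plus one point per additional altered channel; events are returned in
#' descending priority, ties broken by gene id.
#'
#' @param bundle `omics_bundle`.
#' @param catalog Driver catalog tibble (`gene_id`, `role`,
#'   `priority_weight`), e.g. `kb$drivers`.
#' @param methylation_threshold Absolute methylation-score cutoff
#'   (default 1).
#' @param expression_threshold Absolute deregulation cutoff (default 2).
#' @return Tibble of class `driver_events`: `gene_id`, `role`, `channels`,
#'   `severity_grade`, `priority_score` plus per-channel evidence columns.
#' @export
prioritize_drivers <- function(bundle, catalog,
                               methylation_threshold = 1,
                               expression_threshold = 2) {
  muts <- bundle$mutations
  if (!is.null(muts) && nrow(muts) > 0) {
    muts <- muts %>% mutate(grade = grade_mutation(muts))
  }
  events <- purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    g <- catalog$gene_id[i]
    channels <- character(0)
    grade <- "unknown"
    mut_detail <- NA_character_
    if (!is.null(muts) && nrow(muts) > 0) {
      mg <- muts[!is.na(muts$gene_id) & muts$gene_id == g, ]
      if (nrow(mg) > 0) {
        ranked <- factor(mg$grade, levels = SEVERITY_GRADES)
        best <- mg[order(ranked), ][1, ]
        grade <- best$grade
        if (grade %in% c("severe", "damaging", "moderate")) {
          channels <- c(channels, "mutation")
          mut_detail <- sprintf("%s (%s, SIFT=%s, PolyPhen=%s)",
                                best$consequence, best$impact,
                                format(best$sift), format(best$polyphen))
        }
      }
    }
    cna_lr <- NA_real_
    if (!is.null(bundle$cna) && nrow(bundle$cna) > 0) {
      j <- match(g, bundle$cna$gene_id)
      if (!is.na(j) && bundle$cna$call[j] != "neutral") {
        channels <- c(channels, "cna")
        cna_lr <- bundle$cna$log_ratio[j]
      }
    }
    meth <- NA_real_
    if (!is.null(bundle$methylation_diff) &&
        nrow(bundle$methylation_diff) > 0) {
      j <- match(g, bundle$methylation_diff$gene_id)
      if (!is.na(j) &&
          abs(bundle$methylation_diff$score[j]) >= methylation_threshold) {
        channels <- c(channels, "methylation")
        meth <- bundle$methylation_diff$score[j]
      }
    }
    expr <- NA_real_
    if (!is.null(bundle$deregulation) && nrow(bundle$deregulation) > 0) {
      j <- match(g, bundle$deregulation$gene_id)
      if (!is.na(j) &&
          abs(bundle$deregulation$score[j]) >= expression_threshold) {
        channels <- c(channels, "expression")
        expr <- bundle$deregulation$score[j]
      }
    }
    if (length(channels) == 0) return(NULL)
    priority <- catalog$priority_weight[i] * severity_points(grade) +
      (length(channels) - 1)
    tibble(gene_id = g, role = catalog$role[i],
           channels = paste(channels, collapse = "+"),
           severity_grade = grade, priority_score = priority,
           mutation_detail = mut_detail, cna_log_ratio = cna_lr,
           methylation_score = meth, deregulation_score = expr)
  })
  if (nrow(events) == 0) {
    events <- tibble(gene_id = character(), role = character(),
                     channels = character(), severity_grade = character(),
                     priority_score = double(),
                     mutation_detail = character(),
                     cna_log_ratio = double(), methylation_score = double(),
                     deregulation_score = double())
  }
  events <- events %>% arrange(desc(priority_score), gene_id)
  class(events) <- c("driver_events", class(events))
  events
}
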