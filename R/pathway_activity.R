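#' Raw pathway score: weighted sum of deregulation scores
#'
#' The activity of a pathway is approximated by the weighted sum of the
#' deregulation scores of its member genes (weight +1 for activators, -1
#' for inhibitors in the default bundle). Members without a deregulation
#' score are skipped and counted.
#'
#' @param dereg Deregulation tibble (`gene_id`, `score`).
#' @param members Pathway member tibble (`gene_id`, `weight`) for one
#'   pathway.
#' @return List with `raw_score`, `n_used`, `n_members`, `assessable`
#'   (`FALSE` when no member is scored).
#' @export
pathway_raw_score <- function(dereg, members) {
  hit <- match(members$gene_id, dereg$gene_id)
  used <- !is.na(hit)
  if (!any(used)) {
    return(list(raw_score = NA_real_, n_used = 0L,
                n_members = nrow(members), assessable = FALSE))
  }
  list(raw_score = sum(members$weight[used] * dereg$score[hit[used]]),
       n_used = sum(used), n_members = nrow(members), assessable = TRUE)
}

#' Permutation null and empirical P-value for a pathway score
#'
#' The null is built by permuting the gene-to-score assignment over all
#' scored genes: each permutation draws as many scores as the pathway has
#' scored members (without replacement) and recomputes the weighted sum.
#' The two-sided empirical P-value uses the add-one correction
#' `p = (1 + #(|null| >= |observed|)) / (n_perm + 1)`, so `p` is in (0, 1].
#'
#' @param raw_score Observed weighted sum.
#' @param dereg Deregulation tibble supplying the permutation pool (all
#'   scored genes, not only pathway members).
#' @param weights Weights of the scored pathway members.
#' @param n_perm Number of permutations (>= 100).
#' @param exhaustive If `TRUE`, enumerate every ordered assignment of pool
#'   scores to the pathway members instead of sampling (feasible only for
#'   tiny pools; `n_perm` is ignored).
#' @return List with `p_value` and the numeric vector `null_scores`.
#' @export
empirical_pvalue <- function(raw_score, dereg, weights, n_perm = 1000,
                             exhaustive = FALSE) {
  pool <- dereg$score
  m <- length(weights)
  if (m > length(pool)) {
    abort_input("pathway has more scored members than the score pool")
  }
  if (exhaustive) {
    idx <- ordered_selections(length(pool), m)
    null_scores <- vapply(idx, function(ii) sum(weights * pool[ii]),
                          numeric(1))
    n_perm <- length(null_scores)
  } else {
    if (n_perm < 100) abort_input("n_perm must be >= 100")
    null_scores <- vapply(
      seq_len(n_perm),
      function(i) sum(weights * pool[sample.int(length(pool), m)]),
      numeric(1)
    )
  }
  p <- (1 + sum(abs(null_scores) >= abs(raw_score))) / (n_perm + 1)
  list(p_value = p, null_scores = null_scores)
}

# all ordered selections of m items from n (list of index vectors)
ordered_selections <- function(n, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_len(n)) {
    rest <- ordered_selections(n - 1, m - 1)
    remaining <- setdiff(seq_len(n), i)
    out <- c(out, lapply(rest, function(r) c(i, remaining[r])))
  }
  out
}

#' Normalize a raw pathway score to a \[0,1\] activity
#'
#' The activity is the empirical-CDF position of the observed score inside
#' its permutation null: the midrank of the observed score within the
#' pooled set (null scores plus the observation) divided by the pool size
#' plus one. Rank-based and scale-free; no deregulation yields 0.5.
#'
#' @param raw_score Observed weighted sum.
#' @param null_scores Numeric vector from [empirical_pvalue()].
#' @return Activity in \[0, 1\].
#' @export
normalize_activity <- function(raw_score, null_scores) {
  if (length(null_scores) == 0) abort_input("null_scores must be non-empty")
  pool <- c(null_scores, raw_score)
  midrank(raw_score, pool) / (length(pool) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, clipped at 1.
#'
#' @param p_values Numeric vector of raw P-values in (0, 1].
#' @return Adjusted P-values, same order as the input.
#' @export
adjust_bh <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort_input("p-values must lie in (0, 1]")
  }
  pmin(1, p.adjust(p_values, method = "BH"))
}

#' Qualitative activity label
#'
#' `medium` on the closed interval \[0.4, 0.6\], `high` on (0.6, 1\],
#' `low` on \[0, 0.4).
#'
#' @param activity Numeric vector of activities in \[0, 1\].
#' @return Character vector of labels.
#' @export
label_activity <- function(activity) {
  if (any(is.na(activity)) || any(activity < 0 | activity > 1)) {
    abort_input("activity must lie in [0, 1]")
  }
  dplyr::case_when(
    activity > 0.6 ~ "high",
    activity >= 0.4 ~ "medium",
    TRUE ~ "low"
  )
}

#' Score all pathways of a knowledge bundle
#'
#' Runs the full pathway-activity pipeline: weighted raw scores for every
#' pathway, permutation null (gene labels permuted over all scored genes),
#' normalized \[0,1\] activities, two-sided empirical P-values with
#' Benjamini-Hochberg adjustment, and qualitative labels. Pathways with
#' fewer than `min_fraction` of members scored are declared not assessable
#' and carry `NA` activity.
#'
#' @param dereg Deregulation tibble (`gene_id`, `score`).
#' @param kb Knowledge base from [load_knowledge_base()] (or a long pathway
#'   tibble `pathway_id`, `gene_id`, `weight`).
#' @param n_perm Permutations per pathway (default 1000).
#' @param seed Seed for the permutation stream (default 42).
#' @param min_fraction Minimum fraction of members with scores for a
#'   pathway to be assessable (default 0.25).
#' @return Tibble of class `pathway_activity`: `pathway_id`, `raw_score`,
#'   `activity`, `p_value`, `p_adjusted`, `label`, `n_genes_used`,
#'   `n_members`, `n_permutations`, `assessable`.
#' @export
score_pathways <- function(dereg, kb, n_perm = 1000, seed = 42,
                           min_fraction = 0.25) {
  pathways <- if (inherits(kb, "knowledge_base")) kb$pathways else kb
  withr_seed <- !is.null(seed)
  if (withr_seed) set.seed(seed)
  ids <- unique(pathways$pathway_id)
  res <- purrr::map_dfr(ids, function(id) {
    members <- pathways[pathways$pathway_id == id, ]
    rs <- pathway_raw_score(dereg, members)
    assessable <- rs$assessable && rs$n_used / rs$n_members >= min_fraction
    if (!assessable) {
      return(tibble(pathway_id = id, raw_score = rs$raw_score,
                    activity = NA_real_, p_value = NA_real_, label = NA_character_,
                    n_genes_used = rs$n_used, n_members = rs$n_members,
                    n_permutations = n_perm, assessable = FALSE))
    }
    used <- members$gene_id %in% dereg$gene_id
    ep <- empirical_pvalue(rs$raw_score, dereg, members$weight[used], n_perm)
    act <- normalize_activity(rs$raw_score, ep$null_scores)
    tibble(pathway_id = id, raw_score = rs$raw_score, activity = act,
           p_value = ep$p_value, label = label_activity(act),
           n_genes_used = rs$n_used, n_members = rs$n_members,
           n_permutations = n_perm, assessable = TRUE)
  })
  res$p_adjusted <- NA_real_
  ok <- res$assessable
  if (any(ok)) res$p_adjusted[ok] <- adjust_bh(res$p_value[ok])
  res <- res %>% select(pathway_id, raw_score, activity, p_value, p_adjusted,
                        label, n_genes_used, n_members, n_permutations,
                        assessable)
  class(res) <- c("pathway_activity", class(res))
  res
}

#' Rank reference samples by pathway-activity similarity
#'
#' Similarity to the query is the mean squared difference of corresponding
#' pathway activities; references are returned in ascending distance
#' (decreasing similarity), ties broken lexicographically by sample id.
#' Pathways not assessable in the query are dropped pairwise.
#'
#' @param query Named numeric vector of pathway activities (names are
#'   pathway ids), or a `pathway_activity` tibble.
#' @param cohort_activities Tibble/matrix: one row per reference sample
#'   with a `sample_id` column and one column per pathway.
#' @return Tibble `sample_id`, `distance`, ranked.
#' @export
rank_similar_samples <- function(query, cohort_activities) {
  if (inherits(query, "pathway_activity")) {
    q <- setNames(query$activity, query$pathway_id)
  } else {
    q <- query
  }
  q <- q[!is.na(q)]
  ca <- as_tibble(cohort_activities)
  shared <- intersect(names(q), setdiff(names(ca), "sample_id"))
  if (length(shared) == 0) {
    abort_input("no shared assessable pathways between query and cohort")
  }
  mat <- as.matrix(ca[, shared, drop = FALSE])
  d <- rowMeans((mat - matrix(q[shared], nrow(mat), length(shared),
                              byrow = TRUE))^2)
  tibble(sample_id = ca$sample_id, distance = d) %>%
    arrange(distance, sample_id)
}

#' Export radar-plot data for pathway activities
#'
#' Writes (or returns) the JSON consumed by a radar chart: fixed pathway
#' order, activities, adjusted P-values and labels, plus optional reference
#' overlays.
#'
#' @param results `pathway_activity` tibble.
#' @param path Optional output path; `NULL` returns the list.
#' @param references Optional cohort activity tibble (`sample_id` +
#'   pathway columns) to overlay.
#' @return The export list, invisibly when written to `path`.
#' @export
export_radar <- function(results, path = NULL, references = NULL) {
  ok <- results[results$assessable, ]
  out <- list(
    pathway_order = results$pathway_id,
    activities = setNames(as.list(results$activity), results$pathway_id),
    p_adjusted = setNames(as.list(results$p_adjusted), results$pathway_id),
    labels = setNames(as.list(results$label), results$pathway_id),
    not_assessable = results$pathway_id[!results$assessable]
  )
  if (!is.null(references)) {
    out$references <- purrr::pmap(references, function(sample_id, ...) {
      c(list(sample_id = sample_id), list(...))
    })
  }
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(out)
}
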