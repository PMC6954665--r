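#' Build a reference cohort object
#'
#' @param expression Matrix or tibble of expression values, samples in
#'   rows, genes in columns (a `sample_id` column is accepted).
#' @param labels Named character vector or tibble (`sample_id`, `subtype`)
#'   of intrinsic-subtype labels (luminal A / luminal B / HER2-enriched /
#'   basal-like).
#' @param activities Optional cohort pathway-activity tibble.
#' @param tmb Optional named numeric vector of cohort TMB values.
#' @return `reference_cohort` list.
#' @export
reference_cohort <- function(expression, labels, activities = NULL,
                             tmb = NULL) {
  if (is_tibble(expression) || is.data.frame(expression)) {
    expression <- as_tibble(expression)
    if ("sample_id" %in% names(expression)) {
      ids <- expression$sample_id
      expression <- as.matrix(expression[setdiff(names(expression),
                                                 "sample_id")])
      rownames(expression) <- ids
    } else {
      expression <- as.matrix(expression)
    }
  }
  if (is.data.frame(labels)) labels <- setNames(labels$subtype,
                                                labels$sample_id)
  labels <- labels[rownames(expression)]
  if (anyNA(labels)) abort_input("every cohort sample needs a subtype label")
  if (!all(labels %in% SUBTYPES)) {
    abort_input(paste("unknown subtype label:",
                      setdiff(labels, SUBTYPES)[1]))
  }
  structure(list(expression = expression, labels = labels,
                 activities = activities, tmb = tmb),
            class = "reference_cohort")
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat("<reference_cohort>", nrow(x$expression), "samples x",
      ncol(x$expression), "genes\n")
  print(table(x$labels))
  invisible(x)
}

# shared panel preparation: intersect genes, variance-filter on the cohort,
# standardize by cohort mean/sd (the query must not shift the reference
# frame); returns list(cohort_z, query_z)
prepare_panel <- function(query_expression, cohort, n_top_genes = 2000) {
  panel <- intersect(colnames(cohort$expression), names(query_expression))
  if (length(panel) < 0.5 * ncol(cohort$expression)) {
    abort_input(sprintf(
      "query overlaps only %d/%d cohort panel genes (< 50%%)",
      length(panel), ncol(cohort$expression)))
  }
  x <- cohort$expression[, panel, drop = FALSE]
  v <- apply(x, 2, stats::var)
  keep <- v > 0
  x <- x[, keep, drop = FALSE]
  v <- v[keep]
  if (ncol(x) > n_top_genes) {
    x <- x[, order(v, decreasing = TRUE)[seq_len(n_top_genes)], drop = FALSE]
  }
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  cohort_z <- sweep(sweep(x, 2, mu), 2, s, "/")
  query_z <- (query_expression[colnames(x)] - mu) / s
  list(cohort_z = cohort_z, query_z = query_z)
}

#' Embed the query sample with the reference cohort
#'
#' Standardizes the shared gene panel by cohort statistics and computes a
#' two-dimensional embedding of cohort plus query by PCA or t-SNE. PCA is
#' deterministic up to sign; signs are fixed so the largest-magnitude
#' loading of each component is positive. t-SNE is seeded and initialized
#' from the PCA plane so runs are reproducible; perplexity is reduced to
#' `(n - 1) / 3` for small cohorts.
#'
#' @param query_expression Named numeric vector of the query sample's
#'   expression over (a superset of) the cohort gene panel.
#' @param cohort `reference_cohort`.
#' @param method `"pca"` or `"tsne"`.
#' @param seed Seed for the stochastic embedding (default 42).
#' @param n_top_genes Variance-filtered panel size (default 2000).
#' @param perplexity t-SNE perplexity (default 30, auto-reduced).
#' @return Tibble of class `embedding`: `sample_id`, `dim1`, `dim2`,
#'   `subtype`, `is_query`; the method is kept in attribute `method`.
#' @export
embed_samples <- function(query_expression, cohort,
                          method = c("pca", "tsne"), seed = 42,
                          n_top_genes = 2000, perplexity = 30) {
  method <- match.arg(method)
  pp <- prepare_panel(query_expression, cohort, n_top_genes)
  all_z <- rbind(pp$cohort_z, query = pp$query_z)
  n <- nrow(all_z)
  pca <- prcomp(all_z, center = FALSE, scale. = FALSE, rank. = min(50, n - 1))
  # sign convention: largest |loading| of each PC is positive
  for (k in seq_len(ncol(pca$rotation))) {
    j <- which.max(abs(pca$rotation[, k]))
    if (pca$rotation[j, k] < 0) {
      pca$rotation[, k] <- -pca$rotation[, k]
      pca$x[, k] <- -pca$x[, k]
    }
  }
  coords <- if (method == "pca") {
    pca$x[, 1:2, drop = FALSE]
  } else {
    set.seed(seed)
    perp <- min(perplexity, floor((n - 1) / 3))
    init_dims <- min(50, ncol(pca$x))
    fit <- Rtsne::Rtsne(pca$x[, seq_len(init_dims), drop = FALSE],
                        dims = 2, perplexity = perp, pca = FALSE,
                        Y_init = pca$x[, 1:2] / stats::sd(pca$x[, 1]) * 1e-4,
                        check_duplicates = FALSE)
    fit$Y
  }
  if (any(!is.finite(coords))) abort_internal("non-finite embedding")
  ids <- c(rownames(pp$cohort_z), "query")
  out <- tibble(
    sample_id = ids, dim1 = coords[, 1], dim2 = coords[, 2],
    subtype = c(unname(cohort$labels[rownames(pp$cohort_z)]), NA),
    is_query = ids == "query"
  )
  attr(out, "method") <- method
  class(out) <- c("embedding", class(out))
  out
}

#' Call the intrinsic subtype by k-nearest neighbours
#'
#' Distances are Euclidean in the standardized full-panel space (not the
#' 2D embedding). The call is the majority label among the `k` nearest
#' cohort samples; ties break toward the subtype with the smaller mean
#' distance among the tied neighbours.
#'
#' @param query_expression Named numeric query expression vector.
#' @param cohort `reference_cohort`.
#' @param k Number of neighbours (default 15).
#' @param n_top_genes Variance-filtered panel size (default 2000).
#' @return List of class `subtype_call`: `subtype`, `votes` (named
#'   fractions), `neighbors` tibble.
#' @export
call_subtype <- function(query_expression, cohort, k = 15,
                         n_top_genes = 2000) {
  pp <- prepare_panel(query_expression, cohort, n_top_genes)
  d <- sqrt(rowSums(sweep(pp$cohort_z, 2, pp$query_z)^2))
  k <- min(k, length(d))
  nn <- order(d)[seq_len(k)]
  labs <- unname(cohort$labels[rownames(pp$cohort_z)[nn]])
  votes <- sort(table(labs) / k, decreasing = TRUE)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    mean_d <- vapply(top, function(s) mean(d[nn][labs == s]), numeric(1))
    top <- names(which.min(mean_d))
  } else {
    top <- top[1]
  }
  structure(
    list(subtype = top,
         votes = setNames(as.numeric(votes), names(votes)),
         neighbors = tibble(sample_id = rownames(pp$cohort_z)[nn],
                            distance = d[nn], subtype = labs)),
    class = "subtype_call"
  )
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("<subtype_call>", x$subtype, "\n  votes:",
      paste(sprintf("%s=%.2f", names(x$votes), x$votes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export an embedding as plot-ready JSON
#'
#' @param embedding `embedding` tibble from [embed_samples()].
#' @param path Optional output path.
#' @return Export list (invisibly when written).
#' @export
export_embedding <- function(embedding, path = NULL) {
  out <- list(
    method = attr(embedding, "method"),
    samples = purrr::pmap(embedding, function(sample_id, dim1, dim2,
                                              subtype, is_query) {
      list(sample_id = sample_id, x = dim1, y = dim2,
           subtype = subtype, query = is_query)
    })
  )
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out)
}
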