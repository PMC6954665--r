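#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy pathway activity results
#'
#' @param x `pathway_activity` tibble.
#' @param ... Unused.
#' @return Tibble with one row per assessable pathway.
#' @method tidy pathway_activity
#' @export
tidy.pathway_activity <- function(x, ...) {
  as_tibble(x) %>%
    filter(assessable) %>%
    select(pathway_id, activity, p_value, p_adjusted, label, n_genes_used)
}

#' One-row summary of a pathway activity run
#'
#' @param x `pathway_activity` tibble.
#' @param ... Unused.
#' @return Tibble with pathway counts, label tallies and the minimum
#'   adjusted P-value.
#' @method glance pathway_activity
#' @export
glance.pathway_activity <- function(x, ...) {
  ok <- x[x$assessable, ]
  tibble(
    n_pathways = nrow(x), n_assessable = nrow(ok),
    n_high = sum(ok$label == "high"), n_low = sum(ok$label == "low"),
    n_medium = sum(ok$label == "medium"),
    min_p_adjusted = if (nrow(ok) > 0) min(ok$p_adjusted) else NA_real_,
    n_permutations = x$n_permutations[1]
  )
}

#' Tidy a subtype call
#'
#' @param x `subtype_call`.
#' @param ... Unused.
#' @return Tibble of vote fractions per subtype.
#' @method tidy subtype_call
#' @export
tidy.subtype_call <- function(x, ...) {
  tibble(subtype = names(x$votes), vote_fraction = unname(x$votes))
}

#' One-row summary of a subtype call
#'
#' @param x `subtype_call`.
#' @param ... Unused.
#' @return Tibble with the called subtype, its vote fraction and k.
#' @method glance subtype_call
#' @export
glance.subtype_call <- function(x, ...) {
  tibble(subtype = x$subtype, vote_fraction = x$votes[[x$subtype]],
         k = nrow(x$neighbors))
}

#' Tidy drug assessments into one row per evidence item
#'
#' @param x `drug_assessment` tibble.
#' @param ... Unused.
#' @return Long tibble: drug columns plus the unnested evidence items.
#' @method tidy drug_assessment
#' @export
tidy.drug_assessment <- function(x, ...) {
  as_tibble(x) %>%
    select(drug_id, drug_name, category, verdict, items) %>%
    tidyr::unnest(items)
}

#' One-row-per-drug summary of assessments
#'
#' @param x `drug_assessment` tibble.
#' @param ... Unused.
#' @return Tibble without the nested evidence items.
#' @method glance drug_assessment
#' @export
glance.drug_assessment <- function(x, ...) {
  as_tibble(x) %>% select(-items)
}

#' Human-readable drug assessment table
#'
#' Flat TSV-ready summary mirroring the per-drug evidence layout: one row
#' per fired evidence item (plus one row for drugs with no fired item).
#'
#' @param assessments `drug_assessment` tibble.
#' @param path Optional TSV output path.
#' @return The flat tibble (written to `path` when given).
#' @export
drug_summary_table <- function(assessments, path = NULL) {
  flat <- tidy.drug_assessment(assessments) %>%
    group_by(drug_id) %>%
    filter(fired | !any(fired)) %>%
    ungroup() %>%
    select(drug_id, drug_name, category, verdict, kind, subject,
           direction, observed_value, explanation, evidence_ref)
  if (!is.null(path)) readr::write_tsv(flat, path, progress = FALSE)
  flat
}
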