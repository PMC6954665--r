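# default thresholds for "highly"/"lowly" expressed, per score kind
expression_cutoff <- function(score_kind, side) {
  hi <- if (identical(score_kind, "log_fold_change")) 1 else 2
  if (side == "above") hi else -hi
}

dereg_score_of <- function(bundle, gene) {
  d <- bundle$deregulation
  if (is.null(d) || nrow(d) == 0) return(NULL)
  j <- match(gene, d$gene_id)
  if (is.na(j)) return(NULL)
  list(score = d$score[j], kind = d$score_kind[j])
}

gene_mutations_of <- function(bundle, gene) {
  m <- bundle$mutations
  if (is.null(m) || nrow(m) == 0) return(NULL)
  mg <- m[!is.na(m$gene_id) & m$gene_id == gene, ]
  if (nrow(mg) == 0) return(NULL)
  mg
}

#' Evaluate a single drug rule item against a tumor bundle
#'
#' Dispatches on the rule predicate: clinical comparisons
#' (`status_equals`), deregulation thresholds (`expression_above`/`_below`;
#' defaults z >= 2 or |log2 FC| >= 1), mutation predicates
#' (`lof_mutation_present` = any mutation graded severe,
#' `any_mutation_present`, `mutation_absent` = no mutation graded moderate
#' or worse, `severity_at_most` fires when a target mutation exceeds the
#' allowed grade), pathway-label membership (`activity_label_in`) and
#' copy-number thresholds (`copy_number_above`). A rule whose subject
#' cannot be resolved in the bundle returns `fired = FALSE` with an
#' explanation of "not assessable".
#'
#' @param item One rule row (list or one-row tibble) with `kind`,
#'   `subject`, `predicate`, `threshold`, `direction`, `soft`,
#'   `evidence_ref`.
#' @param bundle `omics_bundle`.
#' @param activities `pathway_activity` tibble (may be `NULL`).
#' @return One-row evidence tibble: rule fields plus `observed_value`,
#'   `fired`, `assessable`, `explanation`.
#' @export
evaluate_rule_item <- function(item, bundle, activities = NULL) {
  thr <- item$threshold
  if (is.list(thr) && length(thr) == 1 && !is.list(thr[[1]])) thr <- thr[[1]]
  fired <- FALSE
  assessable <- TRUE
  observed <- NA_character_
  explanation <- ""
  subj <- item$subject

  switch(item$predicate,
    status_equals = {
      cl <- bundle$clinical
      if (is.null(cl) || !subj %in% names(cl) || is.na(cl[[subj]]) ||
          identical(cl[[subj]], "unknown")) {
        assessable <- FALSE
      } else {
        observed <- as.character(cl[[subj]])
        fired <- identical(observed, as.character(thr))
        explanation <- sprintf("clinical %s is '%s'", subj, observed)
      }
    },
    expression_above = ,
    expression_below = {
      sc <- dereg_score_of(bundle, subj)
      if (is.null(sc)) {
        assessable <- FALSE
      } else {
        side <- if (item$predicate == "expression_above") "above" else "below"
        cut <- if (!is.null(thr) && !is.na(suppressWarnings(as.numeric(thr)))) {
          as.numeric(thr)
        } else {
          expression_cutoff(sc$kind, side)
        }
        observed <- format(sc$score, digits = 4)
        fired <- if (side == "above") sc$score >= cut else sc$score <= cut
        explanation <- sprintf("%s deregulation %s (%s), cutoff %s %g",
                               subj, observed, sc$kind,
                               if (side == "above") ">=" else "<=", cut)
      }
    },
    lof_mutation_present = {
      mg <- gene_mutations_of(bundle, subj)
      if (is.null(bundle$mutations) || nrow(bundle$mutations) == 0) {
        assessable <- FALSE
      } else if (!is.null(mg)) {
        grades <- grade_mutation(mg)
        fired <- any(grades == "severe")
        if (fired) {
          k <- which(grades == "severe")[1]
          observed <- mg$consequence[k]
          explanation <- sprintf(
            "%s carries a %s (%s) graded severe: loss of function", subj,
            mg$consequence[k], mg$origin[k])
          if (item$kind == "metabolizing_enzyme") {
            explanation <- paste0(explanation, "; poor metabolizer phenotype")
          }
        } else {
          explanation <- sprintf("no severe mutation in %s", subj)
        }
      } else {
        explanation <- sprintf("no mutation observed in %s", subj)
      }
    },
    any_mutation_present = {
      mg <- gene_mutations_of(bundle, subj)
      if (is.null(bundle$mutations) || nrow(bundle$mutations) == 0) {
        assessable <- FALSE
      } else {
        fired <- !is.null(mg)
        if (fired) {
          observed <- paste(unique(mg$consequence), collapse = ",")
          explanation <- sprintf("%d mutation(s) in %s", nrow(mg), subj)
        } else {
          explanation <- sprintf("no mutation observed in %s", subj)
        }
      }
    },
    mutation_absent = {
      if (is.null(bundle$mutations) || nrow(bundle$mutations) == 0) {
        assessable <- FALSE
      } else {
        mg <- gene_mutations_of(bundle, subj)
        grades <- if (is.null(mg)) character(0) else grade_mutation(mg)
        fired <- !any(grades %in% c("severe", "damaging", "moderate"))
        observed <- if (length(grades) == 0) "wild-type" else
          paste(grades, collapse = ",")
        explanation <- sprintf("%s %s", subj,
                               if (fired) "has no consequential mutation"
                               else "carries consequential mutation(s)")
      }
    },
    severity_at_most = {
      mg <- gene_mutations_of(bundle, subj)
      if (is.null(bundle$mutations) || nrow(bundle$mutations) == 0) {
        assessable <- FALSE
      } else {
        allowed <- match(as.character(thr %||% "moderate"), SEVERITY_GRADES)
        grades <- if (is.null(mg)) character(0) else grade_mutation(mg)
        worst <- if (length(grades) == 0) NA_integer_ else
          min(match(grades, SEVERITY_GRADES))
        # fires when a mutation exceeds the allowed grade
        fired <- !is.na(worst) && worst < allowed
        if (fired) {
          k <- which(match(grades, SEVERITY_GRADES) == worst)[1]
          observed <- SEVERITY_GRADES[worst]
          explanation <- sprintf(
            "%s mutation graded %s exceeds allowed grade '%s' (%s)",
            subj, SEVERITY_GRADES[worst], as.character(thr %||% "moderate"),
            mg$consequence[k])
        } else {
          explanation <- sprintf("no %s mutation above grade '%s'", subj,
                                 as.character(thr %||% "moderate"))
        }
      }
    },
    activity_label_in = {
      if (is.null(activities) || !subj %in% activities$pathway_id) {
        assessable <- FALSE
      } else {
        j <- match(subj, activities$pathway_id)
        if (!isTRUE(activities$assessable[j])) {
          assessable <- FALSE
        } else {
          observed <- activities$label[j]
          fired <- observed %in% unlist(thr)
          explanation <- sprintf("pathway %s activity is '%s'", subj,
                                 observed)
        }
      }
    },
    copy_number_above = {
      cna <- bundle$cna
      if (is.null(cna) || nrow(cna) == 0) {
        assessable <- FALSE
      } else {
        j <- match(subj, cna$gene_id)
        if (is.na(j)) {
          assessable <- FALSE
        } else {
          cut <- as.numeric(thr %||% 0.3)
          observed <- format(cna$log_ratio[j], digits = 4)
          fired <- cna$log_ratio[j] >= cut
          explanation <- sprintf("%s copy-number log-ratio %s, cutoff >= %g",
                                 subj, observed, cut)
        }
      }
    },
    abort_internal(paste("unknown predicate:", item$predicate))
  )
  if (!assessable) {
    fired <- FALSE
    explanation <- sprintf("not assessable: %s not resolvable for %s",
                           subj, item$predicate)
  }
  tibble(
    kind = item$kind, subject = subj, predicate = item$predicate,
    threshold = paste(unlist(thr %||% ""), collapse = ","),
    direction = item$direction, soft = isTRUE(item$soft),
    observed_value = observed, fired = fired, assessable = assessable,
    explanation = explanation, evidence_ref = item$evidence_ref %||% ""
  )
}

#' Assess one drug against the tumor bundle
#'
#' Evaluates every rule item of the drug and aggregates a verdict:
#' `contraindicated` when a decisive contraindication fires (kinds
#' `biomarker` or `metabolizing_enzyme`, unless marked `soft`) or at least
#' two contraindications fire overall; `suggested` when at least one
#' support fires and no contraindication; `conditional` when supports and
#' contraindications both fire below the contraindicated bar (or only soft
#' decisive contraindications fire); `not_assessable` when no item could
#' be evaluated.
#'
#' @param drug_id Drug identifier present in the knowledge base.
#' @param kb `knowledge_base`.
#' @param bundle `omics_bundle`.
#' @param activities `pathway_activity` tibble (optional).
#' @return One-row tibble of class `drug_assessment` columns: `drug_id`,
#'   `drug_name`, `category`, `verdict`, `n_supporting`, `n_contra`, and a
#'   list-column `items` of evidence.
#' @export
assess_drug <- function(drug_id, kb, bundle, activities = NULL) {
  dmeta <- kb$drugs[kb$drugs$drug_id == drug_id, ]
  if (nrow(dmeta) != 1) abort_input(paste("unknown drug:", drug_id))
  rules <- kb$rules[kb$rules$drug_id == drug_id, ]
  items <- purrr::map_dfr(seq_len(nrow(rules)), function(i) {
    evaluate_rule_item(as.list(rules[i, ]), bundle, activities)
  })
  n_sup <- sum(items$fired & items$direction == "supports")
  n_con <- sum(items$fired & items$direction == "contraindicates")
  hard_decisive <- any(items$fired & items$direction == "contraindicates" &
                         items$kind %in% c("biomarker",
                                           "metabolizing_enzyme") &
                         !items$soft)
  soft_decisive <- any(items$fired & items$direction == "contraindicates" &
                         items$soft)
  verdict <- if (!any(items$assessable)) {
    "not_assessable"
  } else if (hard_decisive || n_con >= 2) {
    "contraindicated"
  } else if (n_sup >= 1 && n_con == 0 && !soft_decisive) {
    "suggested"
  } else if (n_con >= 1 || soft_decisive) {
    "conditional"
  } else {
    "not_assessable"
  }
  out <- tibble(drug_id = drug_id, drug_name = dmeta$drug_name,
                category = dmeta$category, verdict = verdict,
                n_supporting = n_sup, n_contra = n_con,
                items = list(items))
  class(out) <- c("drug_assessment", class(out))
  out
}

#' Assess every drug of a knowledge bundle
#'
#' @param kb `knowledge_base`.
#' @param bundle `omics_bundle`.
#' @param activities `pathway_activity` tibble (optional).
#' @param category `"soc"`, `"driver_targeting"` or both (default).
#' @return `drug_assessment` tibble, one row per drug, with
#'   clinical-vs-omics consistency warnings attached as attribute
#'   `consistency_warnings`.
#' @export
assess_drugs <- function(kb, bundle, activities = NULL,
                         category = c("soc", "driver_targeting")) {
  ids <- kb$drugs$drug_id[kb$drugs$category %in% category]
  out <- purrr::map_dfr(ids, assess_drug, kb = kb, bundle = bundle,
                        activities = activities)
  class(out) <- c("drug_assessment", class(out))
  attr(out, "consistency_warnings") <- check_consistency(bundle)
  out
}

#' Spot inconsistencies between clinical markers and omics channels
#'
#' Compares the clinical receptor calls against expression and copy-number
#' evidence for their marker genes (ER/ESR1, PR/PGR, HER2/ERBB2) using the
#' same thresholds as the rule engine, and reports human-readable warnings
#' for every disagreement.
#'
#' @param bundle `omics_bundle` with a clinical record.
#' @return Character vector of warnings (empty when concordant).
#' @export
check_consistency <- function(bundle) {
  cl <- bundle$clinical
  if (is.null(cl)) return(character(0))
  warnings <- character(0)
  pairs <- list(
    list(field = "er_status", gene = "ESR1", label = "ER"),
    list(field = "pr_status", gene = "PGR", label = "PR"),
    list(field = "her2_status", gene = "ERBB2", label = "HER2")
  )
  for (p in pairs) {
    status <- cl[[p$field]]
    if (is.na(status) || status == "unknown") next
    sc <- dereg_score_of(bundle, p$gene)
    if (!is.null(sc)) {
      hi <- expression_cutoff(sc$kind, "above")
      if (status == "negative" && sc$score >= hi) {
        warnings <- c(warnings, sprintf(
          "%s clinically negative but %s strongly overexpressed (score %.2f)",
          p$label, p$gene, sc$score))
      }
      if (status == "positive" && sc$score <= -hi) {
        warnings <- c(warnings, sprintf(
          "%s clinically positive but %s strongly underexpressed (score %.2f)",
          p$label, p$gene, sc$score))
      }
    }
    if (!is.null(bundle$cna) && nrow(bundle$cna) > 0) {
      j <- match(p$gene, bundle$cna$gene_id)
      if (!is.na(j)) {
        if (status == "negative" && bundle$cna$call[j] == "amplified") {
          warnings <- c(warnings, sprintf(
            "%s clinically negative but %s amplified (log-ratio %.2f)",
            p$label, p$gene, bundle$cna$log_ratio[j]))
        }
        if (status == "positive" && bundle$cna$call[j] == "deleted") {
          warnings <- c(warnings, sprintf(
            "%s clinically positive but %s deleted (log-ratio %.2f)",
            p$label, p$gene, bundle$cna$log_ratio[j]))
        }
      }
    }
  }
  warnings
}
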