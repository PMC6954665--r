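#' Path of the bundled default knowledge base
#'
#' @return Directory containing the default knowledge bundle shipped with
#'   the package (pathway gene sets, driver catalog, drug rules, gene lists,
#'   gene models, identifier cross-reference).
#' @export
default_knowledge_root <- function() {
  system.file("extdata", "knowledge", package = "molboard", mustWork = TRUE)
}

read_gmt_pathways <- function(path) {
  lines <- readLines(path, warn = FALSE)
  purrr::map_dfr(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort_input(sprintf("malformed GMT line in %s: '%s'", path,
                          substr(ln, 1, 40)))
    }
    members <- stringr::str_match(parts[-(1:2)],
                                  "^([^|]+)\\|([-0-9.eE+]+)\\|(\\w+)$")
    if (anyNA(members[, 1])) {
      abort_input(sprintf("malformed member entry in pathway %s", parts[1]))
    }
    tibble(pathway_id = parts[1], display_name = parts[2],
           gene_id = members[, 2], weight = as.numeric(members[, 3]),
           role = members[, 4])
  })
}

#' Load and validate a knowledge bundle
#'
#' Reads the declarative knowledge a run depends on: pathway gene sets with
#' weights and activator/inhibitor roles (GMT-style TSV), the driver-gene
#' catalog, the drug-rule tables (17 standard-of-care + 23 driver-targeting
#' drugs in the default bundle), curated gene lists (DNA repair, checkpoint
#' biomarkers, efflux transporters, drug-metabolizing enzymes), gene models
#' for CNA mapping, and the identifier cross-reference. All structural
#' invariants are enforced; a content hash of all files is recorded for
#' report provenance.
#'
#' @param root Directory with the knowledge files; defaults to the bundled
#'   knowledge base.
#' @return A `knowledge_base` list with elements `pathways` (long tibble),
#'   `drivers`, `drugs`, `rules`, `gene_lists`, `gene_models`, `xref`,
#'   `version`, `hash`.
#' @export
load_knowledge_base <- function(root = default_knowledge_root()) {
  need <- c("pathways.gmt", "drivers.tsv", "drug_rules.yaml",
            "gene_lists.yaml", "gene_models.tsv", "id_xref.tsv")
  paths <- file.path(root, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    abort_input(paste("knowledge bundle incomplete, missing:",
                      paste(missing, collapse = ", ")))
  }

  pathways <- read_gmt_pathways(paths[1])
  pw_sizes <- dplyr::count(pathways, pathway_id)
  if (any(pw_sizes$n < 3)) {
    abort_input("every pathway needs >= 3 members")
  }
  bad_w <- pathways %>% group_by(pathway_id) %>%
    summarise(allzero = all(weight == 0) || any(!is.finite(weight)))
  if (any(bad_w$allzero)) abort_input("pathway weights invalid")
  n_pw <- dplyr::n_distinct(pathways$pathway_id)
  if (n_pw != 20) {
    abort_input(sprintf("default bundle must contain 20 pathways, found %d",
                        n_pw))
  }

  drivers <- readr::read_tsv(paths[2], col_types = "ccdc", progress = FALSE)
  names(drivers)[1] <- "gene_id"
  if (anyDuplicated(drivers$gene_id)) {
    abort_input("driver catalog has duplicate gene entries")
  }
  if (!all(drivers$role %in% c("oncogene", "tumor_suppressor", "ambiguous"))) {
    abort_input("driver role outside oncogene/tumor_suppressor/ambiguous")
  }
  if (any(drivers$priority_weight <= 0)) {
    abort_input("driver priority_weight must be positive")
  }

  raw_rules <- yaml::read_yaml(paths[3])
  parse_drugs <- function(entries, category) {
    purrr::map_dfr(entries, function(d) {
      if (is.null(d$rules) || length(d$rules) == 0) {
        abort_input(sprintf("drug '%s' has no rule items", d$drug_id))
      }
      tibble(drug_id = d$drug_id, drug_name = d$drug_name %||% d$drug_id,
             category = category,
             paper_named = isTRUE(d$paper_named), n_rules = length(d$rules))
    })
  }
  parse_rules <- function(entries, category) {
    purrr::map_dfr(entries, function(d) {
      purrr::map_dfr(d$rules, function(r) {
        tibble(
          drug_id = d$drug_id, category = category,
          kind = r$kind, subject = r$subject, predicate = r$predicate,
          threshold = list(r$threshold), direction = r$direction,
          soft = isTRUE(r$soft),
          evidence_ref = r$evidence_ref %||% ""
        )
      })
    })
  }
  drugs <- dplyr::bind_rows(parse_drugs(raw_rules$soc, "soc"),
                            parse_drugs(raw_rules$driver_targeting,
                                        "driver_targeting"))
  rules <- dplyr::bind_rows(parse_rules(raw_rules$soc, "soc"),
                            parse_rules(raw_rules$driver_targeting,
                                        "driver_targeting"))
  n_soc <- sum(drugs$category == "soc")
  n_dt <- sum(drugs$category == "driver_targeting")
  if (n_soc != 17) {
    abort_input(sprintf("default bundle must contain 17 soc drugs, found %d",
                        n_soc))
  }
  if (n_dt != 23) {
    abort_input(sprintf(
      "default bundle must contain 23 driver-targeting drugs, found %d", n_dt))
  }
  valid_kinds <- c("biomarker", "target", "metabolizing_enzyme",
                   "efflux_transporter", "pathway", "genomic_marker")
  valid_preds <- c("status_equals", "expression_above", "expression_below",
                   "lof_mutation_present", "any_mutation_present",
                   "severity_at_most", "activity_label_in",
                   "copy_number_above", "mutation_absent")
  if (!all(rules$kind %in% valid_kinds)) {
    abort_input(paste("unknown rule kind:",
                      setdiff(rules$kind, valid_kinds)[1]))
  }
  if (!all(rules$predicate %in% valid_preds)) {
    abort_input(paste("unknown rule predicate:",
                      setdiff(rules$predicate, valid_preds)[1]))
  }
  if (!all(rules$direction %in% c("supports", "contraindicates"))) {
    abort_input("rule direction must be supports/contraindicates")
  }

  gl_raw <- yaml::read_yaml(paths[4])
  valid_lists <- c("dna_repair", "checkpoint_biomarkers",
                   "efflux_transporters", "drug_metabolizing_enzymes")
  if (!all(names(gl_raw) %in% valid_lists)) {
    abort_input("unknown gene list id in gene_lists.yaml")
  }
  if (anyDuplicated(names(gl_raw)) || any(lengths(gl_raw) == 0)) {
    abort_input("gene lists must be non-empty with unique ids")
  }
  gene_lists <- purrr::imap_dfr(gl_raw, ~ tibble(list_id = .y,
                                                 gene_id = unlist(.x)))

  gene_models <- readr::read_tsv(paths[5], col_types = "ccii",
                                 progress = FALSE)
  if (any(gene_models$start >= gene_models$end)) {
    abort_input("gene model with start >= end")
  }

  xref <- readr::read_tsv(paths[6], col_types = "cccc", progress = FALSE)
  if (!all(c("symbol", "entrez", "ensembl", "uniprot") %in% names(xref))) {
    abort_input("id_xref.tsv must have symbol/entrez/ensembl/uniprot columns")
  }

  # every knowledge gene must resolve in the cross-reference
  referenced <- unique(c(
    pathways$gene_id, drivers$gene_id, gene_lists$gene_id,
    rules$subject[rules$kind != "biomarker" & rules$kind != "pathway"]
  ))
  unresolved <- setdiff(referenced, xref$symbol)
  if (length(unresolved) > 0) {
    abort_input(paste("knowledge genes missing from cross-reference:",
                      paste(head(unresolved, 5), collapse = ", ")))
  }
  pw_subjects <- unique(rules$subject[rules$kind == "pathway"])
  if (!all(pw_subjects %in% pathways$pathway_id)) {
    abort_input("pathway rule subject not in pathway set")
  }

  version <- if (file.exists(file.path(root, "VERSION"))) {
    paste(readLines(file.path(root, "VERSION"), warn = FALSE), collapse = "; ")
  } else "unversioned"
  all_lines <- unlist(purrr::map(sort(paths), readLines, warn = FALSE))
  structure(
    list(pathways = pathways, drivers = drivers, drugs = drugs,
         rules = rules, gene_lists = gene_lists, gene_models = gene_models,
         xref = xref, version = version, hash = content_hash(all_lines)),
    class = "knowledge_base"
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>", x$version, "hash", x$hash, "\n")
  cat(sprintf("  %d pathways, %d driver genes, %d soc + %d driver-targeting drugs\n",
              dplyr::n_distinct(x$pathways$pathway_id), nrow(x$drivers),
              sum(x$drugs$category == "soc"),
              sum(x$drugs$category == "driver_targeting")))
  invisible(x)
}
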