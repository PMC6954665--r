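#' Run the full analysis pipeline on one tumor sample
#'
#' Orchestrates reading and harmonization, driver prioritization, pathway
#' activity scoring, subtype calling, drug assessment and the
#' immunotherapy section, degrading gracefully: stages whose inputs are
#' absent are marked `skipped` in the report rather than failing.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `clinical`, `expression`, `somatic_vcf`, `germline_vcf`, `seg`,
#'   `methylation` (file paths, any subset, at least one omics input);
#'   `knowledge_root` (default bundled knowledge), `n_perm` (default
#'   1000), `seed` (default 42), `exome_mb` (default 30), and optionally
#'   `cohort` (a [reference_cohort()] for subtyping, similarity and the
#'   TMB percentile).
#' @param cohort Optional `reference_cohort`, overriding `config$cohort`.
#' @return A `molboard_report` list; see [write_report()].
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  kb <- load_knowledge_base(config$knowledge_root %||%
                              default_knowledge_root())
  n_perm <- config$n_perm %||% 1000
  seed <- config$seed %||% 42
  exome_mb <- config$exome_mb %||% 30
  cohort <- cohort %||% config$cohort

  clinical <- if (!is.null(config$clinical)) read_clinical(config$clinical)

  dereg <- NULL
  if (!is.null(config$expression)) {
    expr <- read_expression(config$expression)
    dereg <- compute_deregulation(expr)
  }

  mutations <- NULL
  if (!is.null(config$somatic_vcf) || !is.null(config$germline_vcf)) {
    mutations <- dplyr::bind_rows(
      if (!is.null(config$somatic_vcf)) {
        read_vcf(config$somatic_vcf, "somatic")
      },
      if (!is.null(config$germline_vcf)) {
        read_vcf(config$germline_vcf, "germline")
      }
    )
    mutations <- assign_mutation_genes(mutations, kb$gene_models)
  }

  cna <- NULL
  if (!is.null(config$seg)) {
    segments <- read_seg(config$seg)
    cna <- map_segments_to_genes(segments, kb$gene_models)
  }

  meth <- NULL
  if (!is.null(config$methylation)) {
    meth <- compute_methylation_diff(read_methylation(config$methylation))
  }

  bundle <- assemble_bundle(
    clinical = clinical, deregulation = dereg, mutations = mutations,
    cna = cna, methylation_diff = meth, xref = kb$xref,
    provenance = purrr::compact(config[c("clinical", "expression",
                                         "somatic_vcf", "germline_vcf",
                                         "seg", "methylation")])
  )

  drivers <- prioritize_drivers(bundle, kb$drivers)

  activities <- NULL
  if (!is.null(dereg)) {
    activities <- score_pathways(dereg, kb, n_perm = n_perm, seed = seed)
  }

  subtype <- NULL
  similar <- NULL
  if (!is.null(cohort) && !is.null(dereg) && !is.null(config$expression)) {
    expr <- read_expression(config$expression)
    qvec <- setNames(expr$tumor_value, expr$gene_id)
    subtype <- call_subtype(qvec, cohort)
    if (!is.null(cohort$activities) && !is.null(activities)) {
      similar <- rank_similar_samples(activities, cohort$activities)
    }
  }

  assessments <- assess_drugs(kb, bundle, activities)

  tmb <- NULL
  repair <- NULL
  checkpoint <- NULL
  if (!is.null(mutations)) {
    tmb <- compute_tmb(mutations, exome_mb = exome_mb,
                       exon_filter = kb$gene_models,
                       cohort_tmbs = if (!is.null(cohort)) cohort$tmb)
    repair <- repair_gene_status(
      bundle, kb$gene_lists$gene_id[kb$gene_lists$list_id == "dna_repair"])
    checkpoint <- checkpoint_overview(
      bundle,
      kb$gene_lists$gene_id[kb$gene_lists$list_id == "checkpoint_biomarkers"])
  }

  report <- list(
    tool = list(name = "molboard",
                version = as.character(packageVersion("molboard")),
                knowledge_version = kb$version, knowledge_hash = kb$hash),
    run_parameters = list(seed = seed, n_perm = n_perm,
                          exome_mb = exome_mb),
    clinical = if (is.null(clinical)) NULL else as.list(clinical),
    drivers = drivers,
    pathway_activities = activities,
    subtype = if (is.null(subtype)) NULL else
      list(call = subtype$subtype, votes = as.list(subtype$votes)),
    similar_samples = similar,
    drug_assessments = assessments,
    immuno = list(
      tmb = tmb, repair_genes = repair, checkpoint_biomarkers = checkpoint,
      note = paste("neoepitope prediction and HLA typing are external",
                   "steps outside this report")
    ),
    consistency_warnings = attr(assessments, "consistency_warnings"),
    skipped = c(
      if (is.null(dereg)) "pathway_activities",
      if (is.null(subtype)) "subtype",
      if (is.null(mutations)) "immuno",
      if (is.null(cna)) "cna_channel",
      if (is.null(meth)) "methylation_channel"
    )
  )
  class(report) <- "molboard_report"
  report
}

serialize_items <- function(assessments) {
  purrr::pmap(assessments, function(drug_id, drug_name, category, verdict,
                                    n_supporting, n_contra, items) {
    list(drug_id = drug_id, drug_name = drug_name, category = category,
         verdict = verdict, n_supporting = n_supporting,
         n_contra = n_contra,
         items = purrr::transpose(as.list(items)))
  })
}

#' Write a pipeline report as JSON
#'
#' @param report `molboard_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$drivers <- if (nrow(report$drivers) > 0) report$drivers else list()
  out$drug_assessments <- serialize_items(report$drug_assessments)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Export the sunburst overview data
#'
#' Builds the hierarchical ring data summarizing the tumor: pathways in a
#' fixed order, each carrying its activity and its member genes with
#' per-ring values (deregulation, methylation, copy number, mutation
#' grade), oncogene/tumor-suppressor role from the driver catalog and a
#' druggability flag (gene is the subject of a `target`-kind rule). Each
#' gene is assigned to the single pathway where its absolute weight is
#' largest, ties broken by pathway id.
#'
#' @param bundle `omics_bundle`.
#' @param kb `knowledge_base`.
#' @param activities `pathway_activity` tibble (optional).
#' @param path Optional JSON output path.
#' @return Export list (invisibly when written).
#' @export
export_sunburst <- function(bundle, kb, activities = NULL, path = NULL) {
  # gene -> home pathway: largest |weight|, ties by pathway_id
  assign <- kb$pathways %>%
    mutate(absw = abs(weight)) %>%
    arrange(gene_id, desc(absw), pathway_id) %>%
    group_by(gene_id) %>% slice(1) %>% ungroup()
  target_genes <- unique(kb$rules$subject[kb$rules$kind == "target"])
  muts <- bundle$mutations
  rings <- purrr::map(unique(kb$pathways$pathway_id), function(pid) {
    act <- if (!is.null(activities) && pid %in% activities$pathway_id) {
      j <- match(pid, activities$pathway_id)
      list(activity = activities$activity[j], label = activities$label[j])
    } else list(activity = NULL, label = NULL)
    genes <- assign$gene_id[assign$pathway_id == pid]
    gene_nodes <- purrr::map(sort(genes), function(g) {
      grade <- NA_character_
      if (!is.null(muts) && nrow(muts) > 0) {
        mg <- muts[!is.na(muts$gene_id) & muts$gene_id == g, ]
        if (nrow(mg) > 0) {
          gr <- grade_mutation(mg)
          grade <- SEVERITY_GRADES[min(match(gr, SEVERITY_GRADES))]
        }
      }
      val_of <- function(tbl, col = "score") {
        if (is.null(tbl) || nrow(tbl) == 0) return(NULL)
        j <- match(g, tbl$gene_id)
        if (is.na(j)) NULL else tbl[[col]][j]
      }
      rolej <- match(g, kb$drivers$gene_id)
      list(gene = g,
           expression = val_of(bundle$deregulation),
           methylation = val_of(bundle$methylation_diff),
           copy_number = val_of(bundle$cna, "log_ratio"),
           mutation_grade = if (is.na(grade)) NULL else grade,
           driver_role = if (is.na(rolej)) NULL else kb$drivers$role[rolej],
           drug_target = g %in% target_genes)
    })
    list(pathway_id = pid,
         display_name = kb$pathways$display_name[
           match(pid, kb$pathways$pathway_id)],
         activity = act$activity, label = act$label, genes = gene_nodes)
  })
  out <- list(rings = rings)
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(out)
}
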