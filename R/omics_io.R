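#' Read a clinical marker record
#'
#' Clinical markers travel as a YAML mapping or a two-column TSV
#' (`field<TAB>value`). Recognized fields: `patient_id` (required),
#' `er_status`, `pr_status`, `her2_status` (positive/negative/unknown),
#' `menopausal_status` (pre/post/unknown), `histopathological_subtype`,
#' `tumor_size_mm`, `grade` (1-3), `tnm_t`, `tnm_n`, `tnm_m`,
#' `ki67_percent`, `s_phase_fraction` (0-100), `sample_origin`
#' (primary/metastasis), `tumor_cell_fraction` (0-1), `biopsy_date`.
#' Missing fields default to `"unknown"` / `NA`.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or TSV file.
#' @return A one-row tibble of class `clinical_record`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort_input(paste("clinical file not found:", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
  } else {
    tab <- readr::read_tsv(path, col_names = c("field", "value"),
                           col_types = "cc", progress = FALSE)
    raw <- as.list(setNames(tab$value, tab$field))
  }
  rlang::exec(clinical_record, !!!raw)
}

#' Construct and validate a clinical record
#'
#' @param patient_id Required opaque identifier.
#' @param ... Clinical fields, see [read_clinical()].
#' @return One-row tibble of class `clinical_record`.
#' @export
clinical_record <- function(patient_id, ...) {
  if (missing(patient_id) || is.null(patient_id) || !nzchar(patient_id)) {
    abort_input("clinical record requires a patient_id")
  }
  extra <- list(...)
  defaults <- list(
    er_status = "unknown", pr_status = "unknown", her2_status = "unknown",
    menopausal_status = "unknown", histopathological_subtype = NA_character_,
    tumor_size_mm = NA_real_, grade = NA_integer_,
    tnm_t = NA_character_, tnm_n = NA_character_, tnm_m = NA_character_,
    ki67_percent = NA_real_, s_phase_fraction = NA_real_,
    sample_origin = NA_character_, tumor_cell_fraction = NA_real_,
    biopsy_date = NA_character_
  )
  unknown_fields <- setdiff(names(extra), names(defaults))
  if (length(unknown_fields) > 0) {
    warn_molboard(paste("ignoring unknown clinical fields:",
                        paste(unknown_fields, collapse = ", ")))
    extra <- extra[intersect(names(extra), names(defaults))]
  }
  rec <- modifyList(defaults, extra)
  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  rec$tumor_size_mm <- num(rec$tumor_size_mm)
  rec$ki67_percent <- num(rec$ki67_percent)
  rec$s_phase_fraction <- num(rec$s_phase_fraction)
  rec$tumor_cell_fraction <- num(rec$tumor_cell_fraction)
  rec$grade <- if (is.na(rec$grade)) NA_integer_ else as.integer(rec$grade)

  for (f in c("er_status", "pr_status", "her2_status")) {
    if (!rec[[f]] %in% TRISTATE) {
      abort_input(sprintf("%s must be one of %s, got '%s'",
                          f, paste(TRISTATE, collapse = "/"), rec[[f]]))
    }
  }
  if (!rec$menopausal_status %in% MENOPAUSE) {
    abort_input(sprintf("menopausal_status must be pre/post/unknown, got '%s'",
                        rec$menopausal_status))
  }
  chk_range <- function(x, lo, hi, nm) {
    if (!is.na(x) && (x < lo || x > hi)) {
      abort_input(sprintf("%s out of range [%g, %g]: %g", nm, lo, hi, x))
    }
  }
  chk_range(rec$ki67_percent, 0, 100, "ki67_percent")
  chk_range(rec$s_phase_fraction, 0, 100, "s_phase_fraction")
  chk_range(rec$tumor_cell_fraction, 0, 1, "tumor_cell_fraction")
  if (!is.na(rec$tumor_size_mm) && rec$tumor_size_mm < 0) {
    abort_input("tumor_size_mm must be non-negative")
  }
  if (!is.na(rec$grade) && !rec$grade %in% 1:3) {
    abort_input(sprintf("grade must be 1-3, got %d", rec$grade))
  }
  if (!is.na(rec$sample_origin) &&
      !rec$sample_origin %in% c("primary", "metastasis")) {
    abort_input("sample_origin must be primary or metastasis")
  }
  out <- tibble::as_tibble(c(list(patient_id = patient_id), rec))
  class(out) <- c("clinical_record", class(out))
  out
}

#' Read a gene expression table
#'
#' Expects a TSV with a header row; the first column carries gene
#' identifiers, one column the tumor measurement and the remaining numeric
#' columns the control measurements. Duplicate gene rows are collapsed by
#' their mean with a warning.
#'
#' @param path Path to the TSV file.
#' @param layout Optional named list locating columns:
#'   `list(gene = , tumor = , controls = )`. By default the first column is
#'   the gene id, a column named `tumor` (else the second column) is the
#'   tumor sample and all remaining columns are controls.
#' @return Tibble with columns `gene_id`, `tumor_value` and list-column
#'   `control_values` (equal length for every gene).
#' @export
read_expression <- function(path, layout = NULL) {
  if (!file.exists(path)) abort_input(paste("expression file not found:", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2) abort_input("expression table needs >= 2 columns")
  gene_col <- layout$gene %||% names(tab)[1]
  tumor_col <- layout$tumor %||%
    (if ("tumor" %in% names(tab)) "tumor" else names(tab)[2])
  if (!tumor_col %in% names(tab)) {
    abort_input(paste("missing tumor column:", tumor_col))
  }
  control_cols <- layout$controls %||%
    setdiff(names(tab), c(gene_col, tumor_col))
  missing_ctrl <- setdiff(control_cols, names(tab))
  if (length(missing_ctrl) > 0) {
    abort_input(paste("missing control columns:",
                      paste(missing_ctrl, collapse = ", ")))
  }
  for (col in c(tumor_col, control_cols)) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(vals) & !is.na(tab[[col]]) & tab[[col]] != "NA")
    if (length(bad) > 0) {
      abort_input(sprintf(
        "non-numeric expression value '%s' at row %d, column '%s'",
        tab[[col]][bad[1]], bad[1], col))
    }
    if (anyNA(vals) || any(!is.finite(vals))) {
      abort_input(sprintf("missing or non-finite values in column '%s'", col))
    }
    tab[[col]] <- vals
  }
  out <- tibble(
    gene_id = as.character(tab[[gene_col]]),
    tumor_value = tab[[tumor_col]],
    control_values = purrr::pmap(tab[control_cols], ~ unname(c(...)))
  )
  if (length(control_cols) == 0) {
    out$control_values <- rep(list(numeric(0)), nrow(out))
  }
  if (anyDuplicated(out$gene_id)) {
    dups <- unique(out$gene_id[duplicated(out$gene_id)])
    warn_molboard(sprintf(
      "collapsing %d duplicated gene row(s) by mean (e.g. %s)",
      length(dups), dups[1]))
    out <- out %>%
      group_by(gene_id) %>%
      summarise(
        tumor_value = mean(tumor_value),
        control_values = list(unname(colMeans(do.call(rbind,
                                                      control_values)))),
        .groups = "drop"
      )
  }
  out
}

#' Write an expression table (round-trip companion of [read_expression()])
#'
#' @param expr Tibble as returned by [read_expression()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  n_ctrl <- length(expr$control_values[[1]])
  mat <- if (n_ctrl > 0) do.call(rbind, expr$control_values) else NULL
  out <- tibble(gene_id = expr$gene_id, tumor = expr$tumor_value)
  if (n_ctrl > 0) {
    ctrl <- as_tibble(as.data.frame(mat))
    names(ctrl) <- paste0("control_", seq_len(n_ctrl))
    out <- dplyr::bind_cols(out, ctrl)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Compute per-gene deregulation scores
#'
#' With exactly one control per gene the score is a log2 fold-change
#' `log2((tumor + pseudocount) / (control + pseudocount))`; with two or more
#' controls it is a z-score `(tumor - mean(controls)) / sd(controls)` using
#' the sample (n-1) standard deviation. Genes whose controls have zero
#' spread get score 0 and are flagged rather than returning infinities.
#'
#' @param expr Expression tibble from [read_expression()] (or any tibble
#'   with `gene_id`, `tumor_value`, list-column `control_values`).
#' @param pseudocount Positive stabilizer added to numerator and denominator
#'   of the fold-change (default 1; use a small value for beta-scaled data).
#' @return Tibble `gene_id`, `score`, `score_kind`
#'   (`log_fold_change`/`z_score`), `flagged`.
#' @export
compute_deregulation <- function(expr, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  n_ctrl <- lengths(expr$control_values)
  if (any(n_ctrl == 0)) {
    abort_input("every gene needs at least one control value")
  }
  if (length(unique(n_ctrl)) != 1) {
    abort_input("control count must be identical across genes")
  }
  k <- n_ctrl[1]
  if (k == 1) {
    ctrl <- map_dbl(expr$control_values, 1)
    if (any(expr$tumor_value + pseudocount <= 0) ||
        any(ctrl + pseudocount <= 0)) {
      abort_input("log-fold-change needs tumor/control + pseudocount > 0")
    }
    score <- log2((expr$tumor_value + pseudocount) / (ctrl + pseudocount))
    tibble(gene_id = expr$gene_id, score = score,
           score_kind = "log_fold_change", flagged = FALSE)
  } else {
    mu <- map_dbl(expr$control_values, mean)
    s <- map_dbl(expr$control_values, sd)
    flagged <- s == 0
    score <- ifelse(flagged, 0, (expr$tumor_value - mu) / s)
    tibble(gene_id = expr$gene_id, score = score,
           score_kind = "z_score", flagged = flagged)
  }
}

#' Wrap precomputed deregulation scores
#'
#' @param scores Tibble or named numeric vector of per-gene scores.
#' @param score_kind One of `log_fold_change`, `z_score`, `precomputed`.
#' @return Deregulation tibble as from [compute_deregulation()].
#' @export
deregulation_scores <- function(scores, score_kind = "precomputed") {
  score_kind <- match.arg(score_kind,
                          c("precomputed", "log_fold_change", "z_score"))
  if (is.numeric(scores)) {
    scores <- tibble(gene_id = names(scores), score = unname(scores))
  }
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  if (any(!is.finite(scores$score))) {
    abort_input("deregulation scores must be finite")
  }
  tibble(gene_id = as.character(scores$gene_id), score = scores$score,
         score_kind = score_kind,
         flagged = scores$flagged %||% FALSE)
}

# consequence -> default VeP impact class
impact_for_consequence <- function(consequence) {
  dplyr::case_when(
    consequence %in% c("stop_gained", "frameshift_variant",
                       "splice_acceptor_variant",
                       "splice_donor_variant") ~ "HIGH",
    consequence == "missense_variant" ~ "MODERATE",
    consequence == "synonymous_variant" ~ "LOW",
    TRUE ~ "MODIFIER"
  )
}

normalize_consequence <- function(x) {
  x <- sub("&.*$", "", x)          # VeP joins multiple terms with '&'
  x[x == "stop_gain"] <- "stop_gained"
  x[x == "synonymous"] <- "synonymous_variant"
  x[x == "missense"] <- "missense_variant"
  x[x == "frameshift"] <- "frameshift_variant"
  bad <- !x %in% CONSEQUENCES & !is.na(x) & x != ""
  if (any(bad)) {
    warn_molboard(sprintf(
      "%d consequence term(s) outside the controlled vocabulary coerced to 'other' (e.g. '%s')",
      sum(bad), x[bad][1]))
  }
  x[bad | is.na(x) | x == ""] <- "other"
  x
}

parse_score_field <- function(x) {
  # accepts "0.02", "deleterious(0.02)", "" -> NA
  num <- suppressWarnings(as.numeric(x))
  paren <- stringr::str_match(x, "\\(([0-9.eE+-]+)\\)")[, 2]
  out <- ifelse(is.na(num), suppressWarnings(as.numeric(paren)), num)
  out
}

#' Read mutations from a VCF file
#'
#' Parses a VCF 4.x file into one record per alternate allele (multi-allelic
#' sites are split). Consequence annotations are taken from a VeP-style
#' `CSQ` or snpEff-style `ANN` INFO field when present; alternatively a side
#' table `gene_id -> (consequence, impact, sift, polyphen)` can be joined
#' afterwards via [annotate_mutations()]. Unannotated variants get
#' consequence `other` and impact `MODIFIER`.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param origin `"somatic"` or `"germline"`; stamped on every record.
#' @param annotations Optional side-table tibble (or TSV path) with columns
#'   `gene_id`, `consequence`, `impact`, `sift`, `polyphen`.
#' @return Tibble of mutation records: `chrom`, `pos`, `ref`, `alt`,
#'   `origin`, `gene_id`, `consequence`, `impact`, `sift`, `polyphen`.
#' @export
read_vcf <- function(path, origin = c("somatic", "germline"),
                     annotations = NULL) {
  origin <- match.arg(origin)
  if (!file.exists(path)) abort_input(paste("VCF not found:", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8) {
      abort_input(sprintf("malformed VCF line %d: fewer than 8 fields", i))
    }
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort_input(paste("failed to parse VCF:",
                                          conditionMessage(e))))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), origin = character(),
                  gene_id = character(), consequence = character(),
                  impact = character(), sift = double(), polyphen = double()))
  }
  # annotation field layout from the header, if declared
  meta <- vcf@meta
  ann_field <- NULL
  ann_format <- NULL
  for (f in c("CSQ", "ANN")) {
    decl <- grep(sprintf("##INFO=<ID=%s,", f), meta, value = TRUE)
    if (length(decl) == 1) {
      ann_field <- f
      fmt <- stringr::str_match(decl, "Format: ?([^\"]+)")[, 2]
      if (!is.na(fmt)) ann_format <- strsplit(fmt, "|", fixed = TRUE)[[1]]
    }
  }

  recs <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[i] %||% "."
    ann_blocks <- character(0)
    if (!is.null(ann_field)) {
      m <- stringr::str_match(info,
                              sprintf("(?:^|;)%s=([^;]+)", ann_field))[, 2]
      if (!is.na(m)) ann_blocks <- strsplit(m, ",", fixed = TRUE)[[1]]
    }
    purrr::map(alts, function(a) {
      if (identical(a, fix$REF[i])) {
        abort_input(sprintf("ALT equals REF at %s:%s", fix$CHROM[i],
                            fix$POS[i]))
      }
      gene <- NA_character_; cons <- "other"; imp <- NA_character_
      sift_v <- NA_real_; poly_v <- NA_real_
      if (length(ann_blocks) > 0 && !is.null(ann_format)) {
        fields_per_block <- purrr::map(ann_blocks, ~ {
          v <- strsplit(.x, "|", fixed = TRUE)[[1]]
          length(v) <- length(ann_format)
          setNames(v, ann_format)
        })
        allele_of <- map_chr(fields_per_block, ~ .x[["Allele"]] %||% "")
        pick <- which(allele_of == a)
        if (length(pick) == 0) pick <- 1L
        b <- fields_per_block[[pick[1]]]
        gene <- b[["SYMBOL"]] %||% b[["Gene_Name"]] %||% NA_character_
        cons <- normalize_consequence(
          b[["Consequence"]] %||% b[["Annotation"]] %||% "other")
        imp <- b[["IMPACT"]] %||% b[["Annotation_Impact"]] %||% NA_character_
        sift_v <- parse_score_field(b[["SIFT"]] %||% "")
        poly_v <- parse_score_field(b[["PolyPhen"]] %||% "")
      }
      if (is.na(imp) || !imp %in% IMPACTS) imp <- impact_for_consequence(cons)
      if (!is.na(gene) && gene == "") gene <- NA_character_
      tibble(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
             ref = fix$REF[i], alt = a, origin = origin, gene_id = gene,
             consequence = cons, impact = imp, sift = sift_v,
             polyphen = poly_v)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(recs))
  if (any(out$pos < 1)) abort_input("VCF POS must be >= 1")
  if (!is.null(annotations)) out <- annotate_mutations(out, annotations)
  out
}

#' Apply a side-table of consequence annotations to mutation records
#'
#' @param mutations Mutation tibble from [read_vcf()].
#' @param annotations Tibble (or TSV path) with columns `gene_id`,
#'   `consequence`, `impact`, `sift`, `polyphen`.
#' @return Annotated mutation tibble.
#' @export
annotate_mutations <- function(mutations, annotations) {
  if (is.character(annotations)) {
    annotations <- readr::read_tsv(annotations, col_types = readr::cols(),
                                   progress = FALSE)
  }
  ann <- as_tibble(annotations)
  hit <- match(mutations$gene_id, ann$gene_id)
  has <- !is.na(hit)
  if ("consequence" %in% names(ann)) {
    mutations$consequence[has] <-
      normalize_consequence(ann$consequence[hit[has]])
  }
  if ("impact" %in% names(ann)) {
    imp <- ann$impact[hit[has]]
    imp[!imp %in% IMPACTS] <- NA
    mutations$impact[has] <- dplyr::coalesce(
      imp, impact_for_consequence(mutations$consequence[has]))
  }
  for (col in c("sift", "polyphen")) {
    if (col %in% names(ann)) mutations[[col]][has] <- ann[[col]][hit[has]]
  }
  mutations
}

#' Write mutation records as a minimal VCF (round-trip companion)
#'
#' @param mutations Mutation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(mutations, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|Consequence|IMPACT|SYMBOL|SIFT|PolyPhen\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE))
  info <- sprintf("CSQ=%s|%s|%s|%s|%s|%s",
                  mutations$alt, mutations$consequence, mutations$impact,
                  ifelse(is.na(mutations$gene_id), "", mutations$gene_id),
                  fmt_num(mutations$sift), fmt_num(mutations$polyphen))
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  mutations$chrom, mutations$pos, mutations$ref,
                  mutations$alt, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a SEG copy-number file
#'
#' Tab-separated SEG convention: `sample`, `chrom`, `start`, `end`, optional
#' `num_mark`, `seg_mean` (log2 ratio of tumor vs normal copy number).
#' Coordinates are 1-based inclusive throughout; overlap base counts in the
#' gene-mapping step use closed-interval arithmetic on this convention.
#'
#' @param path Path to the SEG file (header row expected).
#' @param origin `"somatic"` or `"germline"`.
#' @return Tibble `chrom`, `start`, `end`, `log_ratio`, `origin`.
#' @export
read_seg <- function(path, origin = c("somatic", "germline")) {
  origin <- match.arg(origin)
  if (!file.exists(path)) abort_input(paste("SEG file not found:", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 5) abort_input("SEG file needs >= 5 columns")
  names(tab) <- tolower(names(tab))
  seg_col <- intersect(c("seg_mean", "seg.mean", "log_ratio"), names(tab))
  if (length(seg_col) == 0) seg_col <- names(tab)[ncol(tab)]
  out <- tibble(
    chrom = as.character(tab[[2]]),
    start = as.integer(tab[[3]]),
    end = as.integer(tab[[4]]),
    log_ratio = as.numeric(tab[[seg_col[1]]]),
    origin = origin
  )
  if (anyNA(out$start) || anyNA(out$end) || anyNA(out$log_ratio)) {
    abort_input("SEG file has non-numeric coordinates or seg_mean")
  }
  if (any(out$start > out$end)) abort_input("SEG segment with start > end")
  if (any(!is.finite(out$log_ratio))) abort_input("non-finite SEG log-ratio")
  out
}

#' Read a per-gene methylation table
#'
#' Whitespace-separated table, first column gene id. Either raw beta values
#' (`tumor` column plus >= 1 control columns, all in \[0,1\]) or a single
#' `score` column of precomputed differential-methylation scores.
#'
#' @param path Path to the table.
#' @return Tibble: either `gene_id`, `tumor_beta`, list-column
#'   `control_betas`, or `gene_id`, `score` for precomputed input.
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) abort_input(paste("methylation file not found:", path))
  tab <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (ncol(tab) < 2) abort_input("methylation table needs >= 2 columns")
  gene <- as.character(tab[[1]])
  if (ncol(tab) == 2 && !tolower(names(tab)[2]) %in% c("tumor", "beta")) {
    score <- as.numeric(tab[[2]])
    if (anyNA(score)) abort_input("non-numeric methylation score")
    return(tibble(gene_id = gene, score = score))
  }
  vals <- purrr::map(tab[-1], as.numeric)
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (anyNA(v)) abort_input(sprintf("non-numeric beta in column %d", j + 1))
    if (any(v < 0 | v > 1)) {
      abort_input(sprintf("beta value out of [0,1] in column '%s': %g",
                          names(tab)[j + 1], v[which(v < 0 | v > 1)[1]]))
    }
  }
  tibble(
    gene_id = gene,
    tumor_beta = vals[[1]],
    control_betas = purrr::pmap(vals[-1], ~ c(...))
  )
}

#' Differential methylation scores from beta values
#'
#' Same contract as [compute_deregulation()] applied to promoter beta
#' values: one control gives a log-fold-quotient with a small pseudocount,
#' several controls give a z-score.
#'
#' @param meth Methylation tibble from [read_methylation()] (raw form).
#' @param pseudocount Stabilizer for the log-fold-quotient (default 0.01,
#'   suited to the \[0,1\] beta scale).
#' @return Tibble `gene_id`, `score`, `score_kind`, `flagged`.
#' @export
compute_methylation_diff <- function(meth, pseudocount = 0.01) {
  if ("score" %in% names(meth)) {
    return(deregulation_scores(meth, "precomputed"))
  }
  expr <- tibble(gene_id = meth$gene_id, tumor_value = meth$tumor_beta,
                 control_values = meth$control_betas)
  compute_deregulation(expr, pseudocount = pseudocount)
}

#' Assemble the harmonized per-gene multi-omics bundle
#'
#' Maps every channel into the unified identifier namespace and packs the
#' harmonized channels with provenance. At least one omics channel is
#' required; absent channels stay `NULL` and downstream stages degrade
#' gracefully.
#'
#' @param clinical `clinical_record` (or `NULL`).
#' @param deregulation Deregulation tibble ([compute_deregulation()]).
#' @param mutations Mutation tibble ([read_vcf()]), any mix of origins.
#' @param cna Gene-level CNA tibble (`gene_id`, `log_ratio`, `call`), e.g.
#'   from [map_segments_to_genes()].
#' @param methylation_diff Differential methylation tibble.
#' @param xref Identifier cross-reference (e.g. `kb$xref`); `NULL` skips
#'   mapping (identifiers assumed unified already).
#' @param provenance Named list of free-text source descriptors.
#' @return An `omics_bundle` list.
#' @export
assemble_bundle <- function(clinical = NULL, deregulation = NULL,
                            mutations = NULL, cna = NULL,
                            methylation_diff = NULL, xref = NULL,
                            provenance = list()) {
  channels <- list(deregulation = deregulation, mutations = mutations,
                   cna = cna, methylation_diff = methylation_diff)
  if (all(map_lgl(channels, is.null))) {
    abort_input("at least one omics channel is required")
  }
  remap <- function(tbl) {
    if (is.null(tbl) || is.null(xref) || nrow(tbl) == 0) return(tbl)
    ok <- !is.na(tbl$gene_id)
    tbl$gene_id[ok] <- unname(map_identifiers(tbl$gene_id[ok], xref))
    tbl
  }
  bundle <- list(
    clinical = clinical,
    deregulation = remap(deregulation),
    mutations = remap(mutations),
    cna = remap(cna),
    methylation_diff = remap(methylation_diff),
    provenance = provenance
  )
  structure(bundle, class = "omics_bundle")
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat("<omics_bundle>\n")
  if (!is.null(x$clinical)) {
    cat("  patient:", x$clinical$patient_id, "\n")
  }
  for (ch in c("deregulation", "mutations", "cna", "methylation_diff")) {
    n <- if (is.null(x[[ch]])) "absent" else paste(nrow(x[[ch]]), "rows")
    cat(sprintf("  %-17s %s\n", ch, n))
  }
  invisible(x)
}
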