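#' Detect the namespace of a set of gene identifiers
#'
#' Classifies each identifier by regex (Ensembl gene IDs `ENSG...`, purely
#' numeric Entrez IDs, UniProt accessions, everything else HGNC symbols) and
#' returns the majority namespace. Identifiers already carrying the reserved
#' `unmapped:` prefix are ignored for the vote.
#'
#' @param ids Character vector of gene identifiers.
#' @return One of `"ensembl"`, `"entrez"`, `"uniprot"`, `"symbol"`.
#' @export
detect_namespace <- function(ids) {
  ids <- ids[!startsWith(ids, "unmapped:")]
  if (length(ids) == 0) return("symbol")
  cls <- dplyr::case_when(
    grepl("^ENSG[0-9]{6,}$", ids) ~ "ensembl",
    grepl("^[0-9]+$", ids) ~ "entrez",
    grepl("^[OPQ][0-9][A-Z0-9]{3}[0-9]$|^[A-NR-Z][0-9][A-Z][A-Z0-9]{2}[0-9]$",
          ids) ~ "uniprot",
    TRUE ~ "symbol"
  )
  tab <- sort(table(cls), decreasing = TRUE)
  major <- names(tab)[1]
  minority <- 1 - tab[[1]] / length(ids)
  if (minority > 0.2) {
    abort_input(sprintf(
      "ambiguous namespace: %.0f%% of identifiers disagree with majority '%s'",
      100 * minority, major))
  }
  major
}

#' Map gene identifiers into the unified (HGNC symbol) namespace
#'
#' All omics channels are keyed by HGNC symbols internally. Input identifiers
#' in Ensembl / Entrez / UniProt namespaces are translated through the
#' bundled cross-reference table; identifiers without a cross-reference entry
#' are preserved under the reserved `unmapped:` prefix so no input is lost.
#' Many-to-one collisions resolve to the lexicographically smallest target
#' with a warning. The mapping is total and idempotent.
#'
#' @param ids Character vector of gene identifiers (one namespace; a minority
#'   share above 20% is a fatal error).
#' @param xref Cross-reference tibble with columns `symbol`, `entrez`,
#'   `ensembl`, `uniprot` (e.g. `knowledge$xref`).
#' @return Named character vector: `ids -> unified identifier`.
#' @export
map_identifiers <- function(ids, xref) {
  stopifnot(is.character(ids))
  out <- ids
  names(out) <- ids
  prefixed <- startsWith(ids, "unmapped:")
  ns <- detect_namespace(ids)
  if (ns == "symbol") {
    # symbols are the unified namespace: known or not, keep them, except
    # that symbols absent from the cross-reference are marked unmapped
    known <- ids %in% xref$symbol | prefixed
    out[!known] <- paste0("unmapped:", ids[!known])
    return(out)
  }
  key <- xref[[ns]]
  hit <- match(ids, key)
  # many-to-one collisions: several input ids hitting the same symbol keep it
  # (that is the harmonization), but a single input id matching several xref
  # rows takes the lexicographically smallest symbol
  dup_rows <- which(duplicated(key) & !is.na(key) & key != "")
  if (length(dup_rows) > 0) {
    for (i in which(ids %in% key[dup_rows])) {
      targets <- sort(xref$symbol[which(key == ids[i])])
      if (length(targets) > 1) {
        warn_molboard(sprintf(
          "identifier '%s' maps to %d symbols; keeping '%s'",
          ids[i], length(targets), targets[1]))
      }
      hit[i] <- which(xref$symbol == targets[1])[1]
    }
  }
  mapped <- !is.na(hit)
  out[mapped] <- xref$symbol[hit[mapped]]
  out[!mapped & !prefixed] <- paste0("unmapped:", ids[!mapped & !prefixed])
  out
}
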