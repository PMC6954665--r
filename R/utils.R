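# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "molboard_input_error", ...)
}

abort_internal <- function(msg, ...) {
  rlang::abort(msg, class = "molboard_internal_error", ...)
}

warn_molboard <- function(msg) {
  rlang::warn(msg, class = "molboard_warning")
}

# Controlled vocabularies shared across modules.
CONSEQUENCES <- c(
  "missense_variant", "stop_gained", "frameshift_variant",
  "splice_acceptor_variant", "splice_donor_variant",
  "synonymous_variant", "other"
)
IMPACTS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
SEVERITY_GRADES <- c("severe", "damaging", "moderate", "low", "unknown")
TRISTATE <- c("positive", "negative", "unknown")
MENOPAUSE <- c("pre", "post", "unknown")
SUBTYPES <- c("luminal A", "luminal B", "HER2-enriched", "basal-like")

# midrank of x within pool (ties get the average rank)
midrank <- function(x, pool) {
  sum(pool < x) + (sum(pool == x) + 1) / 2
}

# deterministic content hash of a character vector (FNV-1a 32-bit, hex).
# Used to fingerprint the knowledge bundle for report provenance.
content_hash <- function(lines) {
  bytes <- utf8ToInt(paste(lines, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b %% 256)
    # h * 16777619 mod 2^32, kept exact in doubles: 16777619 = 2^24 + 403
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
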