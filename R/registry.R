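#' IgG Fc glycoform registry
#'
#' The shorthand codes used for IgG Fc N-glycoforms: \code{NG} denotes the
#' non-glycosylated peptide; \code{G0}/\code{G1}/\code{G2} the number of
#' terminal galactoses (0, 1, 2); suffix \code{F} core fucosylation,
#' \code{N} a bisecting GlcNAc, and \code{S} terminal (mono)sialylation.
#' The registry covers the 20 most common glycoforms plus \code{NG} and
#' carries one motif flag per summary structure.
#'
#' @return A data.frame with one row per code and logical/integer motif
#'   columns: \code{galactose_count}, \code{fucosylated}, \code{bisected},
#'   \code{sialylated}, \code{non_glycosylated}.
#' @export
glycoform_registry <- function() {
  codes <- c(
    "NG",
    "G0", "G0F", "G0N", "G0FN",
    "G1", "G1F", "G1N", "G1FN",
    "G2", "G2F", "G2N", "G2FN",
    "G1S", "G1FS", "G1NS", "G1FNS",
    "G2S", "G2FS", "G2NS", "G2FNS"
  )
  flags <- lapply(codes, parse_glycoform_code)
  out <- do.call(rbind, lapply(flags, as.data.frame))
  out <- cbind(code = codes, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Parse one shorthand code into motif flags.  Errors on codes outside the
# NG / G[012][F][N][S] grammar.
parse_glycoform_code <- function(code) {
  if (code == "NG") {
    return(list(galactose_count = NA_integer_, fucosylated = FALSE,
                bisected = FALSE, sialylated = FALSE, non_glycosylated = TRUE))
  }
  if (!grepl("^G[012]F?N?S?$", code)) {
    stop(sprintf("unknown glycoform code '%s'", code), call. = FALSE)
  }
  list(
    galactose_count  = as.integer(substr(code, 2, 2)),
    fucosylated      = grepl("F", code, fixed = TRUE),
    bisected         = grepl("N", code, fixed = TRUE),
    sialylated       = grepl("S", code, fixed = TRUE),
    non_glycosylated = FALSE
  )
}

# Validate that codes exist in the registry; returns invisibly or errors.
check_glycoform_codes <- function(codes, registry = glycoform_registry()) {
  bad <- setdiff(codes, registry$code)
  if (length(bad) > 0) {
    stop(sprintf("glycoform code(s) not in registry: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(codes)
}
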