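# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stage-specific seed from a root seed so that every stochastic
# stage of the pipeline draws from an independent, reproducible stream.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# z-score columns; returns matrix plus the centering/scaling used.
zscore <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  list(x = sweep(sweep(x, 2, m, "-"), 2, s, "/"), center = m, scale = s)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
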