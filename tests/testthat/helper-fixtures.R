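# Fixtures built in code; no stored data.

# Two-class feature matrix with a planted mean shift on the leading
# features (delta in within-class sd units).
make_two_class <- function(seed, n = 40, p = 30, delta = 2, n_info = 4) {
  set.seed(seed)
  labels <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(stats::rnorm(n * p), n, p)
  if (n_info > 0 && delta != 0) {
    X[labels == "B", seq_len(n_info)] <- X[labels == "B", seq_len(n_info)] + delta
  }
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, labels = labels)
}

# Random regression fixture for PLS property checks.
make_regression <- function(seed, n = 40, p = 25, noise = 0.5) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- stats::rnorm(p) * (stats::runif(p) < 0.3)
  y <- as.numeric(X %*% beta + stats::rnorm(n, 0, noise))
  list(X = X, y = y)
}

# 5PL reference parameters: a steep immunoassay-like sigmoid with a
# two-fold standard dilution series (the usual kit design).
ref_5pl <- function() list(a = 50, d = 30000, c = 200, b = 3, g = 1)
ref_5pl_standards <- function() 12.5 * 2^(0:8)

# Minimal per-image area table from explicit values.
tiny_area_table <- function(patient, marker_area, inter, marker = "CGA",
                            receptor = "FcRn") {
  df <- data.frame(patient_id = patient,
                   image_id = paste0(patient, "_", seq_along(patient)),
                   villous = TRUE)
  df[[paste0(marker, "_area")]] <- marker_area
  df[[paste0(marker, "_", receptor, "_area")]] <- inter
  df
}
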