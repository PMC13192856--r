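# Serological quantification: 5PL standard curves, cord:maternal transfer
# metrics, glycoform summary motifs, and paired enrichment tests.

#' Evaluate a five-parameter logistic curve
#'
#' \code{y = d + (a - d) / (1 + (x/c)^b)^g} with \code{a} the response at
#' zero concentration, \code{d} the response at infinite concentration,
#' \code{c} the inflection scale (concentration units), \code{b} the slope
#' and \code{g} the asymmetry.
#'
#' @param x Concentrations (non-negative).
#' @param a,d,c,b,g 5PL parameters; \code{c > 0}.
#' @return Responses at \code{x}.
#' @export
eval_5pl <- function(x, a, d, c, b, g) {
  if (c <= 0) stop_config("c", "inflection scale must be positive")
  d + (a - d) / (1 + (x / c)^b)^g
}

#' Fit a five-parameter logistic standard curve
#'
#' Least-squares fit of the 5PL model to standard (concentration, response)
#' pairs, as used for multiplexed immunoglobulin isotyping standards.
#'
#' @param concentrations Standard concentrations (> 0), at least 6 spanning
#'   the dynamic range.
#' @param responses Measured responses (e.g. MFI), same length.
#' @param fix_g Optionally fix the asymmetry at a value (e.g. 1 for a 4PL).
#' @return An object of class \code{standard_curve}: the parameter list,
#'   residual summary, and valid response range (open interval between the
#'   asymptotes).
#' @export
fit_5pl <- function(concentrations, responses, fix_g = NULL) {
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must have equal length", call. = FALSE)
  }
  n_par <- if (is.null(fix_g)) 5L else 4L
  if (length(concentrations) < 6) {
    stop(sprintf("need at least 6 standards (got %d) to fit %d parameters",
                 length(concentrations), n_par), call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("standard concentrations must be positive", call. = FALSE)
  }
  ord <- order(concentrations)
  xs <- concentrations[ord]; ys <- responses[ord]
  # Self-starting values: asymptotes from the extreme responses, scale from
  # the concentration nearest the half-response. The (b, g) pair is poorly
  # identified from crude starts, so a small multi-start grid is tried and
  # the lowest-SSR fit kept.
  a0 <- ys[1]; d0 <- ys[length(ys)]
  half <- (a0 + d0) / 2
  c0 <- xs[which.min(abs(ys - half))]
  b_sign <- if (d0 >= a0) 1 else -1
  dat <- data.frame(x = xs, y = ys)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                     ptol = 1e-15)
  starts <- expand.grid(b = b_sign * c(0.5, 1, 2),
                        g = if (is.null(fix_g)) c(0.5, 1, 2) else fix_g)
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch({
      if (is.null(fix_g)) {
        minpack.lm::nlsLM(
          y ~ d + (a - d) / (1 + (x / c)^b)^g, data = dat,
          start = list(a = a0, d = d0, c = c0, b = starts$b[i], g = starts$g[i]),
          lower = c(-Inf, -Inf, 1e-12, -Inf, 1e-6),
          control = ctrl)
      } else {
        minpack.lm::nlsLM(
          y ~ d + (a - d) / (1 + (x / c)^b)^gfix,
          data = cbind(dat, gfix = fix_g),
          start = list(a = a0, d = d0, c = c0, b = starts$b[i]),
          lower = c(-Inf, -Inf, 1e-12, -Inf),
          control = ctrl)
      }
    }, error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("5PL fit failed to converge from every starting point", call. = FALSE)
  }
  fit <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  cf <- as.list(stats::coef(fit))
  if (!is.null(fix_g)) cf$g <- fix_g
  resid <- stats::resid(fit)
  curve <- list(
    a = cf$a, d = cf$d, c = cf$c, b = cf$b, g = cf$g,
    residual_sd = stats::sd(resid),
    residuals = as.numeric(resid),
    response_range = sort(c(cf$a, cf$d)),
    converged = TRUE
  )
  class(curve) <- "standard_curve"
  curve
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("5PL standard curve: a=%.4g d=%.4g c=%.4g b=%.4g g=%.4g (residual sd %.3g)\n",
              x$a, x$d, x$c, x$b, x$g, x$residual_sd))
  invisible(x)
}

#' Invert a 5PL standard curve
#'
#' Closed-form inverse
#' \code{x = c * (((a - d)/(y - d))^(1/g) - 1)^(1/b)}, multiplied by the
#' sample dilution factor. Responses outside the open interval between the
#' asymptotes are flagged \code{NA} rather than extrapolated.
#'
#' @param curve A \code{standard_curve}.
#' @param response Measured responses.
#' @param dilution Dilution factor applied to samples (e.g. 15000 for a
#'   1:15,000 dilution); reported concentrations are scaled back up.
#' @return A data.frame with \code{response}, \code{concentration} and an
#'   \code{in_range} flag.
#' @export
invert_5pl <- function(curve, response, dilution = 1) {
  lo <- min(curve$a, curve$d); hi <- max(curve$a, curve$d)
  in_range <- response > lo & response < hi
  base <- ((curve$a - curve$d) / (response - curve$d))^(1 / curve$g) - 1
  x <- rep(NA_real_, length(response))
  ok <- in_range & base > 0
  x[ok] <- curve$c * base[ok]^(1 / curve$b)
  # responses at the a-side asymptote limit correspond to concentration 0
  x[in_range & base <= 0] <- 0
  data.frame(response = response,
             concentration = x * dilution,
             in_range = in_range)
}

#' Cord:maternal transfer ratios
#'
#' Computes per-dyad, per-feature \code{log10(cord / maternal)} transfer
#' ratios; 0 means equal concentrations in cord and maternal plasma and
#' positive values denote efficient placental transfer.
#'
#' @param maternal,cord Data.frames with a \code{patient_id} column and one
#'   numeric column per feature (e.g. IgG subclass concentrations).
#' @return A long data.frame (\code{patient_id}, \code{feature},
#'   \code{log10_cm}) restricted to matched dyads with positive values;
#'   attributes \code{unmatched} and \code{n_excluded} report drops.
#' @export
cm_ratio <- function(maternal, cord) {
  stopifnot("patient_id" %in% names(maternal), "patient_id" %in% names(cord))
  feats <- intersect(setdiff(names(maternal), "patient_id"),
                     setdiff(names(cord), "patient_id"))
  ids <- intersect(maternal$patient_id, cord$patient_id)
  unmatched <- union(setdiff(maternal$patient_id, ids),
                     setdiff(cord$patient_id, ids))
  m <- maternal[match(ids, maternal$patient_id), feats, drop = FALSE]
  cd <- cord[match(ids, cord$patient_id), feats, drop = FALSE]
  out <- do.call(rbind, lapply(feats, function(f) {
    data.frame(patient_id = ids, feature = f,
               maternal = m[[f]], cord = cd[[f]],
               stringsAsFactors = FALSE)
  }))
  bad <- !(out$maternal > 0 & out$cord > 0) | !is.finite(out$maternal) |
    !is.finite(out$cord)
  if (any(bad)) {
    warning(sprintf("%d dyad-feature pairs with non-positive or missing values excluded",
                    sum(bad)))
  }
  out <- out[!bad, , drop = FALSE]
  out$log10_cm <- log10(out$cord / out$maternal)
  res <- out[, c("patient_id", "feature", "log10_cm")]
  rownames(res) <- NULL
  attr(res, "unmatched") <- unmatched
  attr(res, "n_excluded") <- sum(bad)
  res
}

#' Summary glycan structures
#'
#' Collapses per-glycoform relative abundances into motif summaries:
#' fucosylated, bisected, agalactosylated (G0*), monogalactosylated (G1*),
#' digalactosylated (G2*) and sialylated. Each summary is the sum of the
#' abundances of the codes carrying the motif; the non-glycosylated peptide
#' (NG) contributes to no motif. A code with several motifs (e.g. G2FS)
#' counts once in each matching summary.
#'
#' @param profile Data.frame with key columns (\code{patient_id},
#'   \code{compartment}, \code{subclass}) and one numeric column per
#'   registry code present.
#' @param registry Motif registry; defaults to \code{\link{glycoform_registry}}.
#' @return Data.frame with the key columns and the six summary columns.
#' @export
summary_glycans <- function(profile, registry = glycoform_registry()) {
  keys <- intersect(c("patient_id", "compartment", "subclass"), names(profile))
  codes <- setdiff(names(profile), keys)
  check_glycoform_codes(codes, registry)
  reg <- registry[match(codes, registry$code), ]
  ab <- as.matrix(profile[, codes, drop = FALSE])
  motif_sum <- function(mask) as.numeric(ab %*% as.numeric(mask))
  gal <- function(k) !reg$non_glycosylated & !is.na(reg$galactose_count) &
    reg$galactose_count == k
  out <- profile[, keys, drop = FALSE]
  out$fucosylated       <- motif_sum(reg$fucosylated)
  out$bisected          <- motif_sum(reg$bisected)
  out$agalactosylated   <- motif_sum(gal(0L))
  out$monogalactosylated <- motif_sum(gal(1L))
  out$digalactosylated  <- motif_sum(gal(2L))
  out$sialylated        <- motif_sum(reg$sialylated)
  out
}

#' Paired maternal-vs-cord enrichment
#'
#' Two-sided Wilcoxon signed-rank test of cord minus maternal values per
#' feature over matched dyads, with the median paired difference as the
#' reported direction.
#'
#' @param wide Data.frame with \code{patient_id}, \code{compartment}
#'   (\code{"maternal"}/\code{"cord"}) and numeric feature columns, one row
#'   per (patient, compartment).
#' @param min_dyads Minimum complete dyads per feature (default 5).
#' @return Per-feature data.frame: \code{feature}, \code{n_dyads},
#'   \code{median_diff} (cord - maternal), \code{p_value}, \code{all_ties}.
#' @export
paired_enrichment <- function(wide, min_dyads = 5) {
  stopifnot(all(c("patient_id", "compartment") %in% names(wide)))
  feats <- setdiff(names(wide), c("patient_id", "compartment", "subclass"))
  mat <- wide[wide$compartment == "maternal", , drop = FALSE]
  crd <- wide[wide$compartment == "cord", , drop = FALSE]
  key <- function(d) if ("subclass" %in% names(d))
    paste(d$patient_id, d$subclass, sep = "\r") else as.character(d$patient_id)
  ids <- intersect(key(mat), key(crd))
  mat <- mat[match(ids, key(mat)), , drop = FALSE]
  crd <- crd[match(ids, key(crd)), , drop = FALSE]
  res <- lapply(feats, function(f) {
    d <- crd[[f]] - mat[[f]]
    d <- d[is.finite(d)]
    if (length(d) < min_dyads) {
      stop(sprintf("feature '%s' has %d complete dyads; need >= %d",
                   f, length(d), min_dyads), call. = FALSE)
    }
    ties <- all(d == 0)
    p <- if (ties) 1 else
      suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
    data.frame(feature = f, n_dyads = length(d),
               median_diff = stats::median(d), p_value = p,
               all_ties = ties, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Clinical covariate vs summary-glycan correlation screen
#'
#' Pairwise Spearman correlations between clinical covariates and summary
#' glycan abundances, with two-sided p-values. Pairs with fewer than
#' \code{min_n} complete observations, or with a constant column, are
#' masked (\code{NA}) and flagged.
#'
#' @param clinical Data.frame with \code{patient_id} + numeric covariates.
#' @param glycans Data.frame with \code{patient_id} + numeric glycan columns.
#' @param min_n Minimum paired observations (default 5).
#' @return Long data.frame: covariate, glycan, n, rho, p_value, masked.
#' @export
covariate_glycan_correlations <- function(clinical, glycans, min_n = 5) {
  covs <- setdiff(names(clinical), "patient_id")
  covs <- covs[vapply(clinical[covs], is.numeric, logical(1))]
  gly <- setdiff(names(glycans), "patient_id")
  ids <- intersect(clinical$patient_id, glycans$patient_id)
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  gl <- glycans[match(ids, glycans$patient_id), , drop = FALSE]
  grid <- expand.grid(covariate = covs, glycan = gly,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- cl[[grid$covariate[i]]]; y <- gl[[grid$glycan[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    masked <- n < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
    if (masked) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(covariate = grid$covariate[i], glycan = grid$glycan[i],
               n = n, rho = rho, p_value = p, masked = masked,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
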