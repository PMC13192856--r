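# Gestational trajectory models: cubic receptor-frequency fits with peak
# estimation, and exponential regression of cord IgG accumulation.

#' Third-order polynomial fit of expression vs gestational age
#'
#' Ordinary least squares on \code{[1, g, g^2, g^3]} with R-squared and a
#' pointwise 95% confidence band from the coefficient covariance.
#'
#' @param ga Gestational ages (weeks); at least 6 points with at least 4
#'   distinct values.
#' @param y Expression frequencies (percent) or any response.
#' @return Object of class \code{trajectory_fit} (kind "cubic"):
#'   \code{coefficients} (intercept..cubic), \code{r_squared},
#'   \code{range}, \code{peak_ga}, and a \code{band} function of GA giving
#'   fit/lower/upper.
#' @export
fit_cubic <- function(ga, y) {
  ok <- is.finite(ga) & is.finite(y)
  ga <- ga[ok]; y <- y[ok]
  if (length(ga) < 6) stop("need at least 6 points", call. = FALSE)
  if (length(unique(ga)) < 4) stop("need at least 4 distinct gestational ages",
                                   call. = FALSE)
  fit <- stats::lm(y ~ poly(ga, 3, raw = TRUE))
  beta <- unname(stats::coef(fit))
  # noiseless fixtures trip summary.lm's perfect-fit warning; R^2 is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0  # constant response
  vc <- suppressWarnings(stats::vcov(fit))
  rng <- range(ga)
  band <- function(g) {
    Xg <- cbind(1, g, g^2, g^3)
    fitv <- as.numeric(Xg %*% beta)
    se <- sqrt(rowSums((Xg %*% vc) * Xg))
    tq <- stats::qt(0.975, df = fit$df.residual)
    data.frame(ga = g, fit = fitv, lower = fitv - tq * se,
               upper = fitv + tq * se)
  }
  out <- list(kind = "cubic", coefficients = beta, r_squared = r2,
              range = rng, band = band, df_residual = fit$df.residual,
              coef_se = sqrt(diag(vc)))
  class(out) <- "trajectory_fit"
  out$peak_ga <- peak_location(out)
  out
}

#' Location of the fitted peak within the observed range
#'
#' Argmax of the fitted cubic over the fitted gestational-age range: the
#' interior critical point (root of the derivative quadratic with negative
#' second derivative) when it lies inside the range, otherwise the better
#' endpoint. Extrapolated maxima are never reported.
#'
#' @param fit A cubic \code{trajectory_fit}.
#' @return Gestational age (weeks) of the peak.
#' @export
peak_location <- function(fit) {
  if (fit$kind != "cubic") stop("peak location is defined for cubic fits",
                                call. = FALSE)
  b <- fit$coefficients
  f <- function(g) b[1] + b[2] * g + b[3] * g^2 + b[4] * g^3
  lo <- fit$range[1]; hi <- fit$range[2]
  cand <- c(lo, hi)
  # derivative: b2 + 2 b3 g + 3 b4 g^2; a vanishing cubic term (relative
  # to the quadratic) degrades the root formula, so treat it as quadratic
  A <- 3 * b[4]; B <- 2 * b[3]; C <- b[2]
  if (abs(A) > 1e-12 * (abs(B) / max(hi, 1) + 1e-300)) {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) {
      # numerically stable quadratic roots (avoids cancellation)
      q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
      roots <- c(q / A, if (q != 0) C / q else -B / (2 * A))
      sec <- 2 * b[3] + 6 * b[4] * roots
      cand <- c(cand, roots[sec < 0 & roots > lo & roots < hi])
    }
  } else if (abs(B) > 0) {
    root <- -C / B
    if (b[3] < 0 && root > lo && root < hi) cand <- c(cand, root)
  }
  cand[which.max(f(cand))]
}

#' Exponential regression of concentration vs gestational age
#'
#' Log-linear ordinary least squares \code{ln(conc) = alpha + beta * ga},
#' back-transformed for fitted values; R-squared is reported on the log
#' scale and the 95% confidence band is back-transformed. Non-positive
#' concentrations are excluded with a warning.
#'
#' @param ga Gestational ages (weeks).
#' @param conc Concentrations (> 0).
#' @return \code{trajectory_fit} (kind "exponential") with
#'   \code{coefficients} = c(alpha, beta) on the log-e scale,
#'   \code{r_squared}, \code{range}, \code{band}.
#' @export
fit_exponential <- function(ga, conc) {
  ok <- is.finite(ga) & is.finite(conc)
  if (any(conc[ok] <= 0)) {
    warning(sprintf("%d non-positive concentration(s) excluded", sum(conc[ok] <= 0)))
  }
  ok <- ok & conc > 0
  ga <- ga[ok]; conc <- conc[ok]
  fit <- stats::lm(log(conc) ~ ga)
  beta <- unname(stats::coef(fit))
  vc <- suppressWarnings(stats::vcov(fit))
  rng <- range(ga)
  band <- function(g) {
    Xg <- cbind(1, g)
    fitl <- as.numeric(Xg %*% beta)
    se <- sqrt(rowSums((Xg %*% vc) * Xg))
    tq <- stats::qt(0.975, df = fit$df.residual)
    data.frame(ga = g, fit = exp(fitl), lower = exp(fitl - tq * se),
               upper = exp(fitl + tq * se))
  }
  out <- list(kind = "exponential", coefficients = beta,
              r_squared = suppressWarnings(summary(fit)$r.squared),
              range = rng, band = band,
              df_residual = fit$df.residual)
  class(out) <- "trajectory_fit"
  out
}

#' @export
print.trajectory_fit <- function(x, ...) {
  if (x$kind == "cubic") {
    cat(sprintf("cubic trajectory fit: R^2 = %.3f, peak at %.2f weeks (range %.1f-%.1f)\n",
                x$r_squared, x$peak_ga, x$range[1], x$range[2]))
  } else {
    cat(sprintf("exponential fit: ln(conc) = %.3f + %.4f * GA, R^2 = %.3f\n",
                x$coefficients[1], x$coefficients[2], x$r_squared))
  }
  invisible(x)
}
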