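# NIPALS partial least squares engine: PLSR / PLSDA, outcome-aligned
# orthogonalization, VIP scores, repeated k-fold cross-validation,
# permutation significance, and Q2.

# -- preprocessing ----------------------------------------------------------

pls_preprocess <- function(X, log_transform = FALSE) {
  X <- as.matrix(X)
  offset <- 0
  if (log_transform) {
    if (any(X < 0)) stop("log transform requested on negative data", call. = FALSE)
    if (any(X == 0)) offset <- min(X[X > 0]) / 2
    X <- log10(X + offset)
  }
  z <- zscore(X)
  if (any(z$scale == 0)) {
    stop(sprintf("constant feature(s) after preprocessing: %s",
                 paste(colnames(X)[z$scale == 0], collapse = ", ")),
         call. = FALSE)
  }
  list(x = z$x,
       params = list(log_transform = log_transform, offset = offset,
                     center = z$center, scale = z$scale))
}

apply_pls_preprocess <- function(X, params) {
  X <- as.matrix(X)
  if (params$log_transform) X <- log10(X + params$offset)
  sweep(sweep(X, 2, params$center, "-"), 2, params$scale, "/")
}

# -- NIPALS core ------------------------------------------------------------

nipals_pls <- function(Xs, Yc, n_components, tol = 1e-10, max_iter = 500) {
  n <- nrow(Xs); p <- ncol(Xs); m <- ncol(Yc)
  A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A); Qm <- matrix(0, A, m)
  Tm <- matrix(0, n, A); tt <- numeric(A)
  X <- Xs; Y <- Yc
  a <- 0
  for (comp in seq_len(A)) {
    if (sum(X^2) < 1e-12 * n * p || sum(Y^2) < 1e-14) break
    u <- Y[, which.max(apply(Y, 2, stats::var)), drop = FALSE]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tvec <- X %*% w
      q <- crossprod(Y, tvec) / sum(tvec^2)
      u <- Y %*% q / sum(q^2)
      if (sum((tvec - t_old)^2) < tol * sum(tvec^2)) break
      t_old <- tvec
    }
    tss <- sum(tvec^2)
    if (tss < 1e-12) break
    pvec <- crossprod(X, tvec) / tss
    X <- X - tvec %*% t(pvec)
    Y <- Y - tvec %*% t(q)
    a <- comp
    W[, a] <- w; P[, a] <- pvec; Qm[a, ] <- q; Tm[, a] <- tvec; tt[a] <- tss
  }
  if (a < A) {
    warning(sprintf("rank limited: %d component(s) extracted of %d requested", a, A))
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Qm <- Qm[seq_len(a), , drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
    tt <- tt[seq_len(a)]
  }
  list(W = W, P = P, Q = Qm, T = Tm, tt = tt, n_components = a)
}

#' Fit a PLS regression model (NIPALS)
#'
#' Fits partial least squares regression of a continuous (possibly
#' multivariate) outcome on a feature matrix using NIPALS with deflation.
#' Features are centered and scaled (optionally log10-transformed first);
#' the outcome is centered.
#'
#' @param X Samples-by-features matrix or data.frame.
#' @param y Numeric outcome vector or matrix.
#' @param n_components Number of latent variables (default 2).
#' @param log_transform Log10-transform X before scaling.
#' @return Object of class \code{pls_model}: weights \code{W}, loadings
#'   \code{P}, Y-loadings \code{Q}, scores \code{T}, regression
#'   coefficients \code{B}, per-component explained variance in X and Y,
#'   preprocessing parameters, and outcome spec.
#' @export
fit_pls <- function(X, y, n_components = 2, log_transform = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  if (nrow(X) < n_components + 2) {
    stop("need n >= n_components + 2 samples", call. = FALSE)
  }
  pre <- pls_preprocess(X, log_transform)
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center, "-")
  fit <- nipals_pls(pre$x, Yc, n_components)
  model <- build_pls_model(fit, pre, y_center, outcome = "continuous",
                           classes = NULL, Xs = pre$x, Yc = Yc)
  model
}

#' Fit a PLS discriminant analysis model
#'
#' Class labels are dummy-coded (one column per class), the dummy matrix
#' centered, and a NIPALS PLS2 model fitted. Class prediction is the argmax
#' of the predicted dummy columns.
#'
#' @param X Samples-by-features matrix.
#' @param labels Class labels (>= 2 classes, each with >= 2 members).
#' @param n_components Number of latent variables (default 2).
#' @param log_transform Log10-transform X before scaling.
#' @return \code{pls_model} with \code{outcome = "class"} and the class
#'   levels stored.
#' @export
fit_plsda <- function(X, labels, n_components = 2, log_transform = FALSE) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2)) {
    stop(sprintf("class '%s' has fewer than 2 members",
                 names(counts)[which.min(counts)]), call. = FALSE)
  }
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  X <- as.matrix(X)
  pre <- pls_preprocess(X, log_transform)
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center, "-")
  fit <- nipals_pls(pre$x, Yc, n_components)
  build_pls_model(fit, pre, y_center, outcome = "class",
                  classes = levels(labels), Xs = pre$x, Yc = Yc)
}

build_pls_model <- function(fit, pre, y_center, outcome, classes, Xs, Yc) {
  A <- fit$n_components
  # generalized weights mapping preprocessed X directly to scores
  Wstar <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B <- Wstar %*% fit$Q
  ssy_total <- sum(Yc^2)
  ssx_total <- sum(Xs^2)
  ssy <- vapply(seq_len(A), function(a) {
    sum((fit$T[, a] %o% fit$Q[a, ])^2)
  }, numeric(1))
  ssx <- vapply(seq_len(A), function(a) {
    fit$tt[a] * sum(fit$P[, a]^2)
  }, numeric(1))
  model <- list(
    W = fit$W, P = fit$P, Q = fit$Q, T = fit$T, tt = fit$tt,
    Wstar = Wstar, B = B,
    n_components = A, n_ortho = 0L,
    preprocess = pre$params, y_center = y_center,
    outcome = outcome, classes = classes,
    explained_y = ssy / ssy_total, explained_x = ssx / ssx_total,
    feature_names = colnames(Xs)
  )
  class(model) <- "pls_model"
  model
}

#' Predict from a PLS model
#'
#' @param object A \code{pls_model}.
#' @param newdata Feature matrix with the training columns.
#' @param type \code{"response"} for numeric predictions (dummy-scale for
#'   PLSDA) or \code{"class"} for argmax class labels (PLSDA only).
#' @param ... Unused.
#' @return Numeric matrix or class label vector.
#' @export
predict.pls_model <- function(object, newdata, type = c("response", "class"),
                              ...) {
  type <- match.arg(type)
  Xs <- apply_pls_preprocess(as.matrix(newdata), object$preprocess)
  Yhat <- sweep(Xs %*% object$B, 2, object$y_center, "+")
  if (type == "response") return(Yhat)
  if (object$outcome != "class") stop("type='class' needs a PLSDA model", call. = FALSE)
  object$classes[max.col(Yhat, ties.method = "first")]
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("NIPALS PLS %s model: %d predictive + %d orthogonal component(s), %d features\n",
              if (x$outcome == "class") "discriminant" else "regression",
              x$n_components - x$n_ortho, x$n_ortho, nrow(x$B)))
  cat(sprintf("  variance explained  X: %s   Y: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_x), collapse = " "),
              paste(sprintf("%.1f%%", 100 * x$explained_y), collapse = " ")))
  invisible(x)
}

#' Orthogonalize a fitted PLS model
#'
#' Rotates the fitted score space so that the leading latent variable(s)
#' carry all of the outcome-predictive variation and the remaining
#' components are uncorrelated with the outcome (the outcome-orthogonal
#' block). Fitted values and predictions are exactly invariant: the rotation
#' re-expresses the same subspace, in the spirit of O-PLS, so LV1 aligns
#' with the direction of maximum outcome variation.
#'
#' @param model A fitted \code{pls_model} with at least 2 components.
#' @return The model with rotated scores/loadings/weights, \code{n_ortho}
#'   set, and orthogonal scores in \code{T_ortho}.
#' @export
orthogonalize <- function(model) {
  A <- model$n_components
  if (A < 2) {
    message("single-component model: orthogonalization is a no-op")
    return(model)
  }
  Dhalf <- sqrt(model$tt)
  # V spans the Y-predictive directions of the orthonormalized score space
  V <- Dhalf * model$Q                      # A x m
  sv <- svd(V)
  r <- sum(sv$d > max(sv$d) * 1e-10)
  R1 <- sv$u[, seq_len(r), drop = FALSE]
  # complete to a full orthogonal basis of the score space
  R <- qr.Q(qr(cbind(R1, diag(A))))[, seq_len(A), drop = FALSE]
  R[, seq_len(r)] <- R1
  U <- sweep(model$T, 2, Dhalf, "/")        # orthonormal scores
  Tn <- U %*% R
  Pn <- sweep(model$P, 2, Dhalf, "*") %*% R
  Wn <- sweep(model$Wstar, 2, Dhalf, "*") %*% R
  Qn <- crossprod(R, V)                     # = Tn' Yc since Tn orthonormal basis
  Yc_hat_ss <- rowSums(Qn^2)
  model$T <- Tn; model$P <- Pn; model$W <- Wn; model$Wstar <- Wn
  model$Q <- Qn; model$tt <- rep(1, A)
  model$n_ortho <- A - r
  model$T_ortho <- if (r < A) Tn[, seq.int(r + 1, A), drop = FALSE] else
    Tn[, 0, drop = FALSE]
  model$explained_y <- Yc_hat_ss / sum(Yc_hat_ss) *
    sum(model$explained_y)
  model
}

#' Variable importance in projection
#'
#' \code{VIP_j = sqrt(p * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)}
#' where \code{SSY_a} is the outcome variance explained by component
#' \code{a}. Orthogonal components (zero SSY) do not contribute. The mean
#' of squared VIPs is 1, so VIP > 1 marks above-average influence.
#'
#' @param model Fitted \code{pls_model}.
#' @param signed Orient each VIP by the sign of the feature's LV1 loading
#'   (display convention); default \code{FALSE}.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model, signed = FALSE) {
  W <- model$W
  p <- nrow(W); A <- ncol(W)
  ssy <- vapply(seq_len(A), function(a) {
    sum(model$Q[a, ]^2) * model$tt[a]
  }, numeric(1))
  if (sum(ssy) <= 0) stop("model explains no outcome variance; VIP undefined",
                          call. = FALSE)
  Wn2 <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  vip <- sqrt(p * as.numeric(Wn2 %*% ssy) / sum(ssy))
  names(vip) <- model$feature_names
  if (signed) vip <- vip * sign(model$P[, 1])
  vip
}

# -- validation -------------------------------------------------------------

# Stratified (classification) or plain (regression) fold assignment.
make_folds <- function(y, folds, stratify) {
  n <- length(y)
  f <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds) {
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      } else {
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    }
  } else {
    f <- sample(rep_len(seq_len(folds), n))
  }
  f
}

cv_round <- function(X, y, folds, n_components, log_transform, classification) {
  fold_id <- make_folds(if (classification) as.character(y) else y,
                        folds, classification)
  if (classification) {
    correct <- 0; total <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k; te <- !tr
      if (!any(te)) next
      m <- fit_plsda(X[tr, , drop = FALSE], y[tr],
                     n_components = n_components, log_transform = log_transform)
      pred <- predict(m, X[te, , drop = FALSE], type = "class")
      correct <- correct + sum(pred == as.character(y[te]))
      total <- total + sum(te)
    }
    correct / total
  } else {
    press <- 0; tss <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k; te <- !tr
      if (!any(te)) next
      m <- fit_pls(X[tr, , drop = FALSE], y[tr],
                   n_components = n_components, log_transform = log_transform)
      pred <- predict(m, X[te, , drop = FALSE])
      press <- press + sum((y[te] - pred)^2)
      tss <- tss + sum((y[te] - mean(y[tr]))^2)
    }
    c(press = press, tss = tss)
  }
}

#' Repeated k-fold cross-validation of a PLS model
#'
#' Runs \code{rounds} independent rounds of k-fold cross-validation (an
#' 80:20 split at the default 5 folds). For classification the folds are
#' class-stratified and the per-round statistic is held-out accuracy; for
#' regression it is Q2 (1 - PRESS/TSS). Preprocessing is refit inside every
#' training fold.
#'
#' @param X Feature matrix.
#' @param y Class labels (factor/character) or continuous outcome.
#' @param rounds Number of independent CV rounds (the study design uses
#'   1000; scale down for quick checks).
#' @param folds Number of folds (default 5).
#' @param n_components,log_transform Passed to the fit.
#' @param seed RNG seed; results are deterministic given it.
#' @return List of class \code{pls_validation}: \code{mean}
#'   (mean accuracy or mean Q2), \code{per_round}, \code{rounds},
#'   \code{folds}, \code{seed}, \code{metric}.
#' @export
cross_validate <- function(X, y, rounds = 100, folds = 5, n_components = 2,
                           log_transform = FALSE, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < folds) stop("need at least as many samples as folds", call. = FALSE)
  classification <- is.factor(y) || is.character(y)
  if (classification) {
    y <- as.factor(y)
    if (any(table(y) < folds)) {
      warning("a class is smaller than the fold count; folds degraded to unstratified")
    }
  }
  set.seed(seed)
  per_round <- vapply(seq_len(rounds), function(r) {
    out <- cv_round(X, y, folds, n_components, log_transform, classification)
    if (classification) out else 1 - out["press"] / out["tss"]
  }, numeric(1))
  structure(list(mean = mean(per_round), per_round = per_round,
                 rounds = rounds, folds = folds, seed = seed,
                 metric = if (classification) "accuracy" else "Q2"),
            class = "pls_validation")
}

#' Permutation significance of a PLS(DA) model
#'
#' Builds the true-label cross-validation statistic distribution
#' (\code{rounds} CV rounds) and a null distribution from \code{rounds}
#' models refit after independently shuffling the outcome, each evaluated
#' with one CV round; the two distributions are compared with a two-sided,
#' two-sample t-test.
#'
#' @inheritParams cross_validate
#' @return List of class \code{pls_permutation}: \code{p_value},
#'   \code{true} and \code{permuted} distributions, and the true-model mean
#'   statistic.
#' @export
permutation_test <- function(X, y, rounds = 100, folds = 5, n_components = 2,
                             log_transform = FALSE, seed = 1) {
  X <- as.matrix(X)
  cv <- cross_validate(X, y, rounds = rounds, folds = folds,
                       n_components = n_components,
                       log_transform = log_transform, seed = seed)
  classification <- is.factor(y) || is.character(y)
  if (classification) y <- as.factor(y)
  set.seed(split_seed(seed, "permutation"))
  permuted <- vapply(seq_len(rounds), function(r) {
    yp <- sample(y)
    out <- cv_round(X, yp, folds, n_components, log_transform, classification)
    if (classification) out else 1 - out["press"] / out["tss"]
  }, numeric(1))
  if (stats::sd(cv$per_round) == 0 && stats::sd(permuted) == 0) {
    p <- if (isTRUE(all.equal(mean(cv$per_round), mean(permuted)))) 1 else 0
  } else {
    p <- stats::t.test(cv$per_round, permuted)$p.value
  }
  structure(list(p_value = p, true = cv$per_round, permuted = permuted,
                 mean_statistic = cv$mean, rounds = rounds, seed = seed),
            class = "pls_permutation")
}

#' Cross-validated Q2 for PLS regression
#'
#' \code{Q2 = 1 - PRESS/TSS}, with PRESS summed over held-out folds and TSS
#' computed about each training fold's mean.
#'
#' @inheritParams cross_validate
#' @return Numeric Q2 (always <= 1; <= 0 means no predictive power).
#' @export
q2_score <- function(X, y, n_components = 2, folds = 5, log_transform = FALSE,
                     seed = 1) {
  if (is.factor(y) || is.character(y)) stop("Q2 needs a continuous outcome",
                                            call. = FALSE)
  if (stats::sd(y) == 0) stop("constant outcome", call. = FALSE)
  set.seed(seed)
  out <- cv_round(as.matrix(X), y, folds, n_components, log_transform, FALSE)
  unname(1 - out["press"] / out["tss"])
}
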