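# LASSO stability selection for the two-class glycoform model, and the
# Pearson co-correlate network linking selected to unselected features.

#' One LASSO resampling iteration
#'
#' Draws one without-replacement subsample (default 80%) of the samples,
#' fits an L1-penalized logistic classification with the penalty chosen by
#' inner cross-validation on that subsample, and returns the indices of
#' features with nonzero coefficients.
#'
#' @param X Preprocessed feature matrix.
#' @param labels Two-class labels.
#' @param seed_i Seed for this iteration.
#' @param subsample Fraction of samples drawn (default 0.8).
#' @param lambda_rule \code{"min"} (CV-minimizing penalty) or \code{"1se"}.
#' @param inner_folds Folds for the inner penalty CV (default 5).
#' @return Integer vector of selected feature indices (possibly empty).
#' @export
lasso_iteration <- function(X, labels, seed_i, subsample = 0.8,
                            lambda_rule = c("min", "1se"), inner_folds = 5) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("stability selection needs exactly 2 classes",
                            call. = FALSE)
  set.seed(seed_i)
  # stratified subsample so both classes survive
  idx <- unlist(lapply(levels(y), function(cl) {
    w <- which(y == cl)
    sample(w, max(2, round(length(w) * subsample)))
  }))
  # small-class fold warnings are expected at these dyad counts
  cv <- tryCatch(
    suppressWarnings(
      glmnet::cv.glmnet(X[idx, , drop = FALSE], y[idx], family = "binomial",
                        alpha = 1, nfolds = inner_folds,
                        standardize = TRUE)),
    error = function(e) NULL)
  if (is.null(cv)) return(integer(0))
  s <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = s))[-1]  # drop intercept
  which(beta != 0)
}

#' LASSO stability selection
#'
#' Aggregates \code{\link{lasso_iteration}} over many resamples; the
#' selected set is the features chosen in more than \code{threshold} of the
#' iterations (the study design keeps features selected in >90% of LASSO
#' iterations).
#'
#' @param X Feature matrix (preprocessed: centered/scaled upstream or via
#'   glmnet's internal standardization).
#' @param labels Two-class labels.
#' @param n_iterations Number of resampling iterations (>= 100).
#' @param threshold Selection-frequency threshold (default 0.9, exclusive).
#' @param seed Root seed; per-iteration seeds are derived from it.
#' @param ... Passed to \code{\link{lasso_iteration}}.
#' @return List of class \code{stability_selection}: \code{frequency}
#'   (named per-feature), \code{selected} (names), \code{threshold},
#'   \code{n_iterations}.
#' @export
stability_select <- function(X, labels, n_iterations = 1000, threshold = 0.9,
                             seed = 1, ...) {
  if (n_iterations < 100) stop("need at least 100 iterations", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  counts <- numeric(ncol(X))
  for (i in seq_len(n_iterations)) {
    sel <- lasso_iteration(X, labels, seed_i = split_seed(seed, paste0("lasso", i)),
                           ...)
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / n_iterations
  names(freq) <- colnames(X)
  selected <- names(freq)[freq > threshold]
  if (length(selected) == 0) {
    warning("no feature exceeded the stability threshold; consider lowering it explicitly")
  }
  structure(list(frequency = freq, selected = selected,
                 threshold = threshold, n_iterations = n_iterations,
                 scheme = sprintf("%d x %.0f%% subsampling without replacement",
                                  n_iterations, 100 * list(...)$subsample %||% 80)),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf("LASSO stability selection: %d/%d features above %.0f%% over %d iterations\n",
              length(x$selected), length(x$frequency), 100 * x$threshold,
              x$n_iterations))
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pearson co-correlate network around selected features
#'
#' Computes Pearson correlations between every selected feature and every
#' other feature, keeping edges with two-sided p below \code{alpha}. Nodes
#' are tagged \code{selected} or \code{cocorrelate}; self-edges and
#' duplicate selected-selected pairs are excluded.
#'
#' @param X Feature matrix.
#' @param selected Names (or indices) of the selected features.
#' @param alpha Edge significance threshold (default 0.05).
#' @return List of class \code{correlation_network}: \code{nodes}
#'   (id, category), \code{edges} (source, target, r, p_value, n).
#' @export
cocorrelate_network <- function(X, selected, alpha = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  if (is.numeric(selected)) selected <- colnames(X)[selected]
  if (length(selected) == 0) stop("selected set is empty", call. = FALSE)
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    message(sprintf("constant feature(s) excluded: %s",
                    paste(colnames(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
    selected <- intersect(selected, colnames(X))
  }
  edges <- list()
  seen <- character(0)
  for (s in selected) {
    for (f in setdiff(colnames(X), s)) {
      key <- paste(sort(c(s, f)), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      ct <- stats::cor.test(X[, s], X[, f])
      if (ct$p.value < alpha) {
        edges[[length(edges) + 1]] <- data.frame(
          source = s, target = f, r = unname(ct$estimate),
          p_value = ct$p.value, n = sum(stats::complete.cases(X[, c(s, f)])),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               r = numeric(0), p_value = numeric(0), n = integer(0))
  node_ids <- union(selected, unique(c(edges$source, edges$target)))
  nodes <- data.frame(id = node_ids,
                      category = ifelse(node_ids %in% selected,
                                        "selected", "cocorrelate"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 method = "pearson"),
            class = "correlation_network")
}
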