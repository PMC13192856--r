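# Unsupervised clinical clustering: log/center/scale preprocessing, PCA,
# WSS-guided k-means on the first two PCs, and projection of a second
# cohort into the training cohort's latent space.

#' Preprocess a clinical covariate table
#'
#' Removes rows with incomplete observations, one-hot encodes categorical
#' covariates, log10-transforms positive continuous covariates (adding an
#' offset of half the smallest positive observed value where zeros occur),
#' and z-scores every retained column. Constant columns are dropped with a
#' warning. The returned parameters reproduce the transform exactly on new
#' data (\code{\link{apply_preprocess}}).
#'
#' @param table Data.frame with \code{patient_id} plus covariates.
#' @param log_features Names of features to log-transform; default all
#'   numeric non-negative features.
#' @return List: \code{x} (matrix, rows named by patient_id), \code{params}
#'   (per-feature transform, offset, center, scale, encoding levels),
#'   \code{removed} (ids of incomplete rows).
#' @export
preprocess_clinical <- function(table, log_features = NULL) {
  stopifnot("patient_id" %in% names(table))
  feats <- setdiff(names(table), "patient_id")
  complete <- stats::complete.cases(table[feats])
  removed <- table$patient_id[!complete]
  if (length(removed) > 0) {
    message(sprintf("%d patient(s) removed for incomplete observations",
                    length(removed)))
  }
  tab <- table[complete, , drop = FALSE]
  cols <- list(); params <- list()
  for (f in feats) {
    v <- tab[[f]]
    if (is.numeric(v)) {
      do_log <- if (is.null(log_features)) all(v >= 0) else f %in% log_features
      offset <- 0
      if (do_log) {
        if (any(v == 0)) offset <- min(v[v > 0]) / 2
        v <- log10(v + offset)
      }
      cols[[f]] <- v
      params[[f]] <- list(kind = "numeric",
                          transform = if (do_log) "log10" else "identity",
                          offset = offset)
    } else {
      lev <- sort(unique(as.character(v)))
      # one indicator per level beyond the first (full dummies are collinear)
      for (l in lev[-1]) {
        nm <- paste0(f, "_", l)
        cols[[nm]] <- as.numeric(as.character(v) == l)
      }
      params[[f]] <- list(kind = "categorical", levels = lev)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- tab$patient_id
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("constant feature(s) dropped: %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- zscore(x)
  list(x = z$x,
       params = list(features = params, center = z$center, scale = z$scale,
                     columns = colnames(x)),
       removed = removed)
}

#' Apply frozen preprocessing parameters to new data
#'
#' Transforms a new cohort with the training cohort's preprocessing
#' parameters (same log offsets, centers and scales), as required for a
#' shared latent space.
#'
#' @param table New data.frame with \code{patient_id} and every training
#'   feature.
#' @param params The \code{params} element returned by
#'   \code{\link{preprocess_clinical}}.
#' @return Matrix with rows named by patient_id, columns as in training.
#' @export
apply_preprocess <- function(table, params) {
  feats <- names(params$features)
  missing <- setdiff(feats, names(table))
  if (length(missing) > 0) {
    stop(sprintf("new table lacks feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  complete <- stats::complete.cases(table[feats])
  tab <- table[complete, , drop = FALSE]
  cols <- list()
  for (f in feats) {
    p <- params$features[[f]]
    if (p$kind == "numeric") {
      v <- tab[[f]]
      if (p$transform == "log10") v <- log10(v + p$offset)
      cols[[f]] <- v
    } else {
      for (l in p$levels[-1]) {
        cols[[paste0(f, "_", l)]] <- as.numeric(as.character(tab[[f]]) == l)
      }
    }
  }
  x <- do.call(cbind, cols)[, params$columns, drop = FALSE]
  rownames(x) <- tab$patient_id
  sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
}

#' Principal component analysis of a preprocessed matrix
#'
#' Singular-value decomposition of the (already centered) matrix; loadings
#' are orthonormal and explained-variance fractions non-increasing.
#'
#' @param x Preprocessed matrix (samples x features).
#' @return List of class \code{latent_model}: \code{loadings},
#'   \code{scores}, \code{explained_variance}, \code{rank}.
#' @export
fit_pca <- function(x) {
  if (nrow(x) < 3 || ncol(x) < 2) {
    stop("PCA needs at least 3 rows and 2 columns", call. = FALSE)
  }
  xc <- sweep(x, 2, colMeans(x), "-")
  sv <- svd(xc)
  ev <- sv$d^2 / sum(sv$d^2)
  rank <- sum(sv$d > max(dim(xc)) * max(sv$d) * .Machine$double.eps)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  scores <- xc %*% loadings
  model <- list(loadings = loadings, scores = scores,
                explained_variance = ev, rank = rank,
                feature_means = colMeans(x))
  class(model) <- "latent_model"
  model
}

#' Choose K by the within-cluster sum-of-squares elbow
#'
#' Computes the k-means WSS curve for k = 1..k_max (best of \code{n_init}
#' restarts each) and returns the elbow as the k with maximum second
#' difference of the curve. A weak elbow (second-difference contrast below
#' \code{weak_threshold} of the total drop) is flagged.
#'
#' @param scores2d Two-column score matrix.
#' @param k_max Largest k considered (>= 2, < n).
#' @param seed,n_init k-means restart control.
#' @param weak_threshold Contrast fraction below which the elbow is weak.
#' @return List: \code{k}, \code{wss} (length k_max), \code{weak_elbow}.
#' @export
select_k_wss <- function(scores2d, k_max = 6, seed = 1, n_init = 20,
                         weak_threshold = 0.2) {
  n <- nrow(scores2d)
  if (k_max < 2) stop("k_max must be at least 2", call. = FALSE)
  if (k_max >= n) stop("k_max must be smaller than the sample size", call. = FALSE)
  set.seed(seed)
  wss <- vapply(seq_len(k_max), function(k) {
    if (k == 1) return(sum(scale(scores2d, scale = FALSE)^2))
    stats::kmeans(scores2d, centers = k, nstart = n_init,
                  iter.max = 100)$tot.withinss
  }, numeric(1))
  d2 <- wss[seq_len(k_max - 2)] - 2 * wss[seq_len(k_max - 2) + 1] +
    wss[seq_len(k_max - 2) + 2]
  k <- which.max(d2) + 1L
  contrast <- max(d2) / (wss[1] - wss[k_max])
  list(k = k, wss = wss, weak_elbow = contrast < weak_threshold)
}

#' K-means clustering on latent scores
#'
#' Lloyd's algorithm with \code{n_init} random restarts keeping the best
#' within-cluster sum of squares; deterministic given the seed.
#'
#' @param scores2d Score matrix (typically PC1-PC2).
#' @param k Number of clusters.
#' @param seed,n_init Restart control.
#' @return List: \code{labels}, \code{centroids}, \code{tot_withinss}.
#' @export
kmeans_cluster <- function(scores2d, k, seed = 1, n_init = 50) {
  if (k > nrow(scores2d)) stop("k exceeds the sample size", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(scores2d, centers = k, nstart = n_init, iter.max = 100)
  list(labels = km$cluster, centroids = km$centers,
       tot_withinss = km$tot.withinss)
}

#' Fit the full clinical latent model
#'
#' Preprocess, PCA, WSS-guided choice of K (unless fixed), and k-means on
#' PC1-PC2.
#'
#' @param table Clinical covariate table with \code{patient_id}.
#' @param k Fixed number of clusters, or \code{NULL} to choose by the WSS
#'   elbow.
#' @param k_max,seed Passed to \code{\link{select_k_wss}} /
#'   \code{\link{kmeans_cluster}}.
#' @return \code{latent_model} with preprocessing params, kmeans fields and
#'   training labels added.
#' @export
fit_latent_model <- function(table, k = NULL, k_max = 6, seed = 1) {
  pre <- preprocess_clinical(table)
  model <- fit_pca(pre$x)
  model$preprocess <- pre$params
  s2 <- model$scores[, 1:2, drop = FALSE]
  if (is.null(k)) {
    sel <- select_k_wss(s2, k_max = k_max, seed = seed)
    k <- sel$k
    model$wss <- sel$wss
    model$weak_elbow <- sel$weak_elbow
  }
  km <- kmeans_cluster(s2, k, seed = seed)
  model$k <- k
  model$centroids <- km$centroids
  model$labels <- km$labels
  model
}

#' Project a new cohort into the training latent space
#'
#' New data are transformed with the TRAINING preprocessing parameters,
#' mean-centered with the training feature means, and multiplied by the
#' training loadings.
#'
#' @param model A fitted \code{latent_model} with \code{preprocess}.
#' @param new_table New cohort table containing every training feature.
#' @return Score matrix for the new cohort.
#' @export
project_cohort <- function(model, new_table) {
  x <- apply_preprocess(new_table, model$preprocess)
  sweep(x, 2, model$feature_means, "-") %*% model$loadings
}

#' Assign samples to the nearest cluster centroid
#'
#' Each sample is assigned the cluster whose centroid is nearest in
#' Euclidean distance in the (PC1, PC2) latent space; ties go to the
#' lowest cluster index.
#'
#' @param scores2d Score matrix (columns matching the centroids).
#' @param model Fitted \code{latent_model} with centroids.
#' @return Integer cluster labels.
#' @export
assign_clusters <- function(scores2d, model) {
  if (is.null(model$centroids)) stop("model has no fitted centroids", call. = FALSE)
  cen <- model$centroids
  s <- scores2d[, seq_len(ncol(cen)), drop = FALSE]
  d2 <- outer(rowSums(s^2), rep(1, nrow(cen))) +
    outer(rep(1, nrow(s)), rowSums(cen^2)) - 2 * s %*% t(cen)
  apply(d2, 1, which.min)  # which.min takes the first (lowest) index on ties
}
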