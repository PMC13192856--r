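# Covariate-controlled partial Pearson correlation networks between Fc
# receptor expression features and transfer metrics.

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the residuals of \code{x} and \code{y} after least-squares
#' regression on an intercept plus the covariate matrix \code{Z}; the
#' two-sided p-value uses the t statistic with \code{n - 2 - |Z|} degrees
#' of freedom. With an empty \code{Z} this is the plain Pearson
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param Z Covariate matrix/data.frame (columns = controlled covariates),
#'   or \code{NULL}.
#' @return List: \code{r}, \code{p_value}, \code{n_effective} (complete
#'   cases used), \code{df}.
#' @export
partial_corr <- function(x, y, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) {
    Zm <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    Zm <- as.matrix(Z)
  }
  ok <- is.finite(x) & is.finite(y) &
    (if (ncol(Zm) == 0) TRUE else apply(is.finite(Zm), 1, all))
  n <- sum(ok)
  q <- ncol(Zm)
  if (n <= q + 3) stop(sprintf("need more than |Z| + 3 = %d complete cases (got %d)",
                               q + 3, n), call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  if (q > 0) {
    Zs <- cbind(1, Zm[ok, , drop = FALSE])
    qrz <- qr(Zs)
    if (qrz$rank < ncol(Zs)) {
      warning("rank-deficient covariate matrix; reduced to its column space")
    }
    rx <- stats::residuals(stats::lm.fit(Zs, xs))
    ry <- stats::residuals(stats::lm.fit(Zs, ys))
  } else {
    rx <- xs - mean(xs); ry <- ys - mean(ys)
  }
  # residual variance at numerical-noise level means the variable is
  # (near-)perfectly explained by Z
  if (stats::sd(rx) <= 1e-10 * stats::sd(xs) ||
      stats::sd(ry) <= 1e-10 * stats::sd(ys)) {
    return(list(r = NA_real_, p_value = NA_real_, n_effective = n, df = n - 2 - q,
                degenerate = TRUE))
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - q
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p_value = p, n_effective = n, df = df, degenerate = FALSE)
}

#' Build a covariate-controlled partial correlation network
#'
#' Computes the partial Pearson correlation, controlling for the given
#' covariates, for every cross pair of features between two tables matched
#' on \code{patient_id}; edges are kept when \code{|r| > r_min} and
#' \code{p < p_max} (defaults 0.15 and 0.1). Complete cases are used per
#' pair and the per-edge n is recorded; nodes without a surviving edge are
#' retained but flagged isolated.
#'
#' @param table_a,table_b Data.frames with \code{patient_id} + numeric
#'   feature columns (e.g. receptor expression frequencies and transfer
#'   ratios).
#' @param covariates Data.frame with \code{patient_id} + covariate columns
#'   (typically gestational age, maternal age, gravidity, pregravid BMI and
#'   EPDS), or \code{NULL} for marginal correlations.
#' @param r_min,p_max Edge-trimming thresholds.
#' @return \code{correlation_network}: nodes (id, category, isolated),
#'   edges (source, target, r, p_value, n_effective), thresholds, the
#'   controlled covariate names, and the skipped-pair count.
#' @export
build_pcn <- function(table_a, table_b, covariates = NULL,
                      r_min = 0.15, p_max = 0.1) {
  fa <- setdiff(names(table_a), "patient_id")
  fb <- setdiff(names(table_b), "patient_id")
  ids <- intersect(table_a$patient_id, table_b$patient_id)
  if (!is.null(covariates)) ids <- intersect(ids, covariates$patient_id)
  a <- table_a[match(ids, table_a$patient_id), , drop = FALSE]
  b <- table_b[match(ids, table_b$patient_id), , drop = FALSE]
  Z <- if (is.null(covariates)) NULL else
    as.matrix(covariates[match(ids, covariates$patient_id),
                         setdiff(names(covariates), "patient_id"),
                         drop = FALSE])
  q <- if (is.null(Z)) 0 else ncol(Z)
  edges <- list(); skipped <- 0
  for (x in fa) {
    for (y in fb) {
      res <- tryCatch(partial_corr(a[[x]], b[[y]], Z),
                      error = function(e) NULL)
      if (is.null(res) || isTRUE(res$degenerate) || !is.finite(res$r)) {
        skipped <- skipped + 1
        next
      }
      if (abs(res$r) > r_min && res$p_value < p_max) {
        edges[[length(edges) + 1]] <- data.frame(
          source = x, target = y, r = res$r, p_value = res$p_value,
          n_effective = res$n_effective, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0), r = numeric(0),
               p_value = numeric(0), n_effective = integer(0))
  nodes <- data.frame(
    id = c(fa, fb),
    category = c(rep("table_a", length(fa)), rep("table_b", length(fb))),
    stringsAsFactors = FALSE)
  nodes$isolated <- !(nodes$id %in% c(edges$source, edges$target))
  structure(list(nodes = nodes, edges = edges,
                 r_min = r_min, p_max = p_max,
                 covariates = if (is.null(Z)) character(0) else colnames(Z),
                 method = if (q > 0) "partial_pearson" else "pearson",
                 n_skipped = skipped),
            class = "correlation_network")
}

#' Marginal vs partial correlation comparison
#'
#' For every cross pair between the two tables, reports the marginal
#' Pearson correlation, the covariate-controlled partial correlation, the
#' absolute change, and whether the sign flipped — the diagnostic used to
#' show confounding by gestational age.
#'
#' @inheritParams build_pcn
#' @return Data.frame: source, target, r_marginal, r_partial, delta_abs,
#'   sign_change.
#' @export
compare_marginal_partial <- function(table_a, table_b, covariates) {
  fa <- setdiff(names(table_a), "patient_id")
  fb <- setdiff(names(table_b), "patient_id")
  ids <- Reduce(intersect, list(table_a$patient_id, table_b$patient_id,
                                covariates$patient_id))
  a <- table_a[match(ids, table_a$patient_id), , drop = FALSE]
  b <- table_b[match(ids, table_b$patient_id), , drop = FALSE]
  Z <- as.matrix(covariates[match(ids, covariates$patient_id),
                            setdiff(names(covariates), "patient_id"),
                            drop = FALSE])
  out <- list()
  for (x in fa) {
    for (y in fb) {
      m <- partial_corr(a[[x]], b[[y]], NULL)
      p <- partial_corr(a[[x]], b[[y]], Z)
      out[[length(out) + 1]] <- data.frame(
        source = x, target = y,
        r_marginal = m$r, r_partial = p$r,
        delta_abs = abs(p$r - m$r),
        sign_change = sign(p$r) != sign(m$r) & m$r != 0 & p$r != 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Export a correlation network
#'
#' Writes a \code{correlation_network} as GraphML (via igraph) and/or an
#' edge-list CSV.
#'
#' @param network A \code{correlation_network}.
#' @param graphml,edgelist Output paths (either may be \code{NULL}).
#' @return The igraph object, invisibly.
#' @export
write_network <- function(network, graphml = NULL, edgelist = NULL) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edgelist)) utils::write.csv(network$edges, edgelist,
                                           row.names = FALSE)
  invisible(g)
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("%s network: %d nodes, %d edges",
              x$method %||% "correlation", nrow(x$nodes), nrow(x$edges)))
  if (!is.null(x$r_min)) cat(sprintf(" (|r| > %.2f, p < %.2f)", x$r_min, x$p_max))
  if (length(x$covariates %||% character(0)) > 0) {
    cat("; controlled for", paste(x$covariates, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
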