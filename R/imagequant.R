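# Image quantification: cell-type-specific Fc receptor expression from
# per-image area and cell-density tables (HALO-style exports).

# Column naming convention used throughout:
#   marker area:         "<marker>_area"              (mm^2)
#   intersection area:   "<marker>_<receptor>_area"   (mm^2)
#   pair intersection:   "<marker>_<r1>_<r2>_area"
#   cell densities:      "<marker>_density", "<marker>_<receptor>_density"
# plus key columns patient_id, image_id and a logical `villous` flag.

marker_for_cell_type <- function(cell_type) {
  switch(cell_type,
         STB = "CGA", EC = "CD34", HBC = "CD163",
         stop(sprintf("unknown cell type '%s'", cell_type), call. = FALSE))
}

#' Area-based receptor expression frequency
#'
#' For area-quantified cell types (STB via CGA, EC via CD34), the per-image
#' expression frequency is the marker-and-receptor colocalized area divided
#' by the marker area, times 100; the per-patient value is the unweighted
#' mean over that patient's images.
#'
#' @param aq Per-image area table (see column convention in the source).
#' @param cell_type "STB" or "EC".
#' @param receptor Receptor name, e.g. "FcRn", "FcgRIIIa", "FcgRIIb".
#' @return Data.frame: \code{patient_id}, \code{frequency} (percent),
#'   \code{n_images}. Patients whose marker area is zero in every image are
#'   excluded with a warning.
#' @export
expression_frequency_area <- function(aq, cell_type, receptor) {
  marker <- marker_for_cell_type(cell_type)
  acol <- paste0(marker, "_area")
  icol <- paste0(marker, "_", receptor, "_area")
  if (!all(c(acol, icol) %in% names(aq))) {
    stop(sprintf("columns '%s'/'%s' not found in area table", acol, icol),
         call. = FALSE)
  }
  ok <- aq[[acol]] > 0
  freq <- ifelse(ok, aq[[icol]] / aq[[acol]] * 100, NA_real_)
  agg <- stats::aggregate(freq, by = list(patient_id = aq$patient_id),
                          FUN = function(v) mean(v, na.rm = TRUE))
  n_img <- stats::aggregate(ok, by = list(patient_id = aq$patient_id), FUN = sum)
  out <- data.frame(patient_id = agg$patient_id, frequency = agg$x,
                    n_images = n_img$x)
  dropped <- out$patient_id[out$n_images == 0]
  if (length(dropped) > 0) {
    warning(sprintf("patient(s) with all-zero %s area excluded: %s",
                    marker, paste(dropped, collapse = ", ")))
    out <- out[out$n_images > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Cell-density-based receptor expression frequency
#'
#' For Hofbauer cells (CD163, enumerated as cells/mm^2), the per-image
#' frequency is the receptor-positive density as a percentage of total HBC
#' density; per-patient value is the unweighted mean over images. Images
#' with zero HBC density are skipped for this metric.
#'
#' @inheritParams expression_frequency_area
#' @export
expression_frequency_cells <- function(aq, receptor, cell_type = "HBC") {
  marker <- marker_for_cell_type(cell_type)
  dcol <- paste0(marker, "_density")
  icol <- paste0(marker, "_", receptor, "_density")
  if (!all(c(dcol, icol) %in% names(aq))) {
    stop(sprintf("columns '%s'/'%s' not found in table", dcol, icol),
         call. = FALSE)
  }
  ok <- aq[[dcol]] > 0
  freq <- ifelse(ok, aq[[icol]] / aq[[dcol]] * 100, NA_real_)
  agg <- stats::aggregate(freq, by = list(patient_id = aq$patient_id),
                          FUN = function(v) mean(v, na.rm = TRUE))
  n_img <- stats::aggregate(ok, by = list(patient_id = aq$patient_id), FUN = sum)
  out <- data.frame(patient_id = agg$patient_id, frequency = agg$x,
                    n_images = n_img$x)
  out <- out[out$n_images > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise receptor colocalization partition
#'
#' Partitions the marker-positive area of a cell type into the four
#' receptor-pair compartments R1+R2+, R1+R2-, R1-R2+, R1-R2- by
#' inclusion-exclusion, each expressed as a percentage of marker area.
#' Per-image percentages are averaged per patient.
#'
#' @param aq Per-image area table.
#' @param cell_type "STB" or "EC".
#' @param receptor_pair Character vector of two receptor names, in the
#'   column-name order used for the pair intersection.
#' @return Data.frame: patient_id, pp, pn, np, nn (percent; sum 100).
#' @export
coexpression_partition <- function(aq, cell_type, receptor_pair) {
  stopifnot(length(receptor_pair) == 2)
  marker <- marker_for_cell_type(cell_type)
  acol <- paste0(marker, "_area")
  c1 <- paste0(marker, "_", receptor_pair[1], "_area")
  c2 <- paste0(marker, "_", receptor_pair[2], "_area")
  cp <- paste0(marker, "_", receptor_pair[1], "_", receptor_pair[2], "_area")
  need <- c(acol, c1, c2, cp)
  if (!all(need %in% names(aq))) {
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(aq)), collapse = ", ")),
         call. = FALSE)
  }
  tol <- 1e-9
  if (any(aq[[cp]] > aq[[c1]] + tol) || any(aq[[cp]] > aq[[c2]] + tol)) {
    stop("pair intersection area exceeds a single-receptor area", call. = FALSE)
  }
  ok <- aq[[acol]] > 0
  pct <- function(v) ifelse(ok, v / aq[[acol]] * 100, NA_real_)
  pp <- pct(aq[[cp]])
  pn <- pct(aq[[c1]] - aq[[cp]])
  np <- pct(aq[[c2]] - aq[[cp]])
  nn <- 100 - pp - pn - np
  agg <- function(v) stats::aggregate(
    v, by = list(patient_id = aq$patient_id),
    FUN = function(z) mean(z, na.rm = TRUE))$x
  ids <- stats::aggregate(pp, by = list(patient_id = aq$patient_id),
                          FUN = function(z) mean(z, na.rm = TRUE))$patient_id
  out <- data.frame(patient_id = ids, pp = agg(pp), pn = agg(pn),
                    np = agg(np), nn = agg(nn))
  out <- out[is.finite(out$pp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative receptor expression ratio with paired test
#'
#' Compares two receptor expression frequencies within the same patients:
#' reports the per-patient \code{log10(numerator/denominator)}, the ratio
#' of group means and the mean of per-patient ratios, and a two-sided
#' Wilcoxon signed-rank test of the paired frequencies.
#'
#' @param profile Data.frame with \code{patient_id} and the two frequency
#'   columns named \code{<cell_type>_<receptor>}.
#' @param numerator,denominator Receptor names.
#' @param cell_type Cell type prefix used in column names.
#' @return List: \code{per_patient} (patient_id, log10_ratio),
#'   \code{ratio_of_means}, \code{mean_of_ratios}, \code{p_value},
#'   \code{n_excluded} (zero-frequency patients dropped).
#' @export
receptor_ratio <- function(profile, numerator, denominator, cell_type) {
  ncol_ <- paste0(cell_type, "_", numerator)
  dcol_ <- paste0(cell_type, "_", denominator)
  stopifnot(all(c(ncol_, dcol_) %in% names(profile)))
  num <- profile[[ncol_]]; den <- profile[[dcol_]]
  ok <- is.finite(num) & is.finite(den) & num > 0 & den > 0
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    warning(sprintf("%d patient(s) excluded from ratio (zero or missing frequency)",
                    n_excl))
  }
  num <- num[ok]; den <- den[ok]
  diffs <- num - den
  p <- if (all(diffs == 0)) 1 else
    suppressWarnings(stats::wilcox.test(num, den, paired = TRUE,
                                        exact = FALSE)$p.value)
  list(
    per_patient = data.frame(patient_id = profile$patient_id[ok],
                             log10_ratio = log10(num / den)),
    ratio_of_means = mean(num) / mean(den),
    mean_of_ratios = mean(num / den),
    p_value = p,
    n_excluded = n_excl
  )
}

#' Build a per-patient expression profile
#'
#' Combines area-based (STB, EC) and cell-density-based (HBC) receptor
#' expression frequencies into a single patients-by-features table, joined
#' with gestational age and trimester.
#'
#' @param aq Per-image area/density table.
#' @param meta Data.frame with \code{patient_id} and
#'   \code{gestational_age_weeks}.
#' @param receptors Receptor names to quantify (default the panel's three).
#' @return Data.frame keyed by patient_id with one \code{<cell>_<receptor>}
#'   column per combination plus gestational_age_weeks and trimester.
#' @export
build_expression_profile <- function(aq, meta,
                                     receptors = c("FcRn", "FcgRIIIa", "FcgRIIb")) {
  out <- data.frame(patient_id = sort(unique(aq$patient_id)))
  add <- function(out, df, nm) {
    out[[nm]] <- df$frequency[match(out$patient_id, df$patient_id)]
    out
  }
  for (r in receptors) {
    for (ct in c("STB", "EC")) {
      col <- paste0(marker_for_cell_type(ct), "_", r, "_area")
      if (col %in% names(aq)) {
        out <- add(out, expression_frequency_area(aq, ct, r),
                   paste0(ct, "_", r))
      }
    }
    col <- paste0("CD163_", r, "_density")
    if (col %in% names(aq)) {
      out <- add(out, expression_frequency_cells(aq, r), paste0("HBC_", r))
    }
  }
  out$gestational_age_weeks <-
    meta$gestational_age_weeks[match(out$patient_id, meta$patient_id)]
  out$trimester <- assign_trimester(out$gestational_age_weeks)
  out
}

#' Trimester from gestational age
#'
#' T1 < 14 weeks, 14 <= T2 < 28, T3 >= 28; boundary values go to the later
#' trimester.
#' @param ga_weeks Gestational ages in weeks.
#' @return Integer vector in {1, 2, 3}.
#' @export
assign_trimester <- function(ga_weeks) {
  ifelse(ga_weeks < 14, 1L, ifelse(ga_weeks < 28, 2L, 3L))
}
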