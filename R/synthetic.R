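# Synthetic cohort generator: clinical covariates with planted clusters,
# dyadic serology with cluster-dependent transfer offsets, maternal/cord
# glycoform compositions with planted log-odds shifts, per-image area and
# cell-density tables following planted cubic gestational trajectories,
# and 5PL standard curves. Every planted parameter is returned as ground
# truth so downstream estimators can be verified without patient data.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: three
#' clinical clusters separated by 4 z-units with 30 patients each, 14
#' glycan dyads, gestational ages spanning 9-41 weeks sampled by trimester
#' strata, cluster-dependent cord:maternal log10 offsets of +0.3/0/-0.3,
#' maternal-enriched sialylation and cord-enriched agalactosylation, and
#' cubic receptor trajectories peaking near 20 weeks for the barrier-cell
#' receptors.
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @param n_patients_per_cluster,n_clusters Planted cluster design.
#' @param cluster_effect_sd Separation of cluster means, z-units.
#' @param n_dyads Maternal-cord dyads for the glycan tables.
#' @param n_images Images per patient in the area tables.
#' @param cm_offsets Per-cluster log10 cord:maternal offsets (recycled to
#'   n_clusters).
#' @param glycan_shift Named log-odds shifts (cord vs maternal) per
#'   glycoform code; defaults shift sialylated codes toward maternal and
#'   agalactosylated toward cord.
#' @param trajectory_coeffs Named list (\code{"<cell>_<receptor>"}) of cubic
#'   coefficients on gestational-age weeks; default panel built with
#'   \code{\link{cubic_trajectory}}.
#' @param freq_patient_sd Patient-level deviation (percentage points) of
#'   true receptor frequency around the cubic trajectory.
#' @param transfer_link Named coefficients (\code{"<cell>_<receptor>"}):
#'   contribution of the patient's standardized receptor-frequency
#'   deviation to the log10 cord:maternal ratio, planting a
#'   receptor-transfer partial correlation given gestational age.
#' @param noise_sd Named noise levels per table family
#'   (clinical log-sd, serology log10-sd, glycoforms log-odds-sd, areas
#'   relative-sd, mfi relative-to-range-sd).
#' @param ga_range Gestational-age range (weeks), within (4, 42).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_patients_per_cluster = 30,
                       n_clusters = 3,
                       cluster_effect_sd = 4,
                       n_dyads = 14,
                       n_images = 4,
                       cm_offsets = c(0.3, 0, -0.3),
                       freq_patient_sd = 5,
                       transfer_link = c(STB_FcRn = 0.1, EC_FcgRIIb = 0.1),
                       glycan_shift = NULL,
                       trajectory_coeffs = NULL,
                       noise_sd = c(clinical = 1, serology = 0.05,
                                    glycoforms = 0.1, areas = 0.03,
                                    mfi = 0.02),
                       ga_range = c(9, 41)) {
  if (n_clusters < 1) stop_config("n_clusters", "must be >= 1")
  if (any(noise_sd < 0)) stop_config("noise_sd", "must be non-negative")
  if (ga_range[1] <= 4 || ga_range[2] >= 42 || ga_range[1] >= ga_range[2]) {
    stop_config("ga_range", "must be an increasing interval within (4, 42)")
  }
  if (is.null(glycan_shift)) {
    reg <- glycoform_registry()
    glycan_shift <- c(
      stats::setNames(rep(-0.3, sum(reg$sialylated)), reg$code[reg$sialylated]),
      stats::setNames(rep(0.3, sum(!reg$non_glycosylated &
                                     !is.na(reg$galactose_count) &
                                     reg$galactose_count == 0)),
                      reg$code[!reg$non_glycosylated &
                                 !is.na(reg$galactose_count) &
                                 reg$galactose_count == 0]))
  }
  check_glycoform_codes(names(glycan_shift))
  if (is.null(trajectory_coeffs)) {
    trajectory_coeffs <- list(
      STB_FcRn     = cubic_trajectory(20, 70, 30, ga_range),
      STB_FcgRIIIa = cubic_trajectory(20, 50, 30, ga_range),
      STB_FcgRIIb  = cubic_trajectory(12, 45, 25, ga_range),
      EC_FcRn      = cubic_trajectory(20, 60, 25, ga_range),
      EC_FcgRIIb   = cubic_trajectory(20, 55, 25, ga_range),
      EC_FcgRIIIa  = cubic_trajectory(30, 30, 15, ga_range),
      HBC_FcRn     = cubic_trajectory(41, 60, 15, ga_range),
      HBC_FcgRIIIa = cubic_trajectory(25, 40, 10, ga_range),
      HBC_FcgRIIb  = cubic_trajectory(18, 35, 10, ga_range)
    )
  }
  cfg <- list(seed = seed,
              n_patients_per_cluster = n_patients_per_cluster,
              n_clusters = n_clusters,
              cluster_effect_sd = cluster_effect_sd,
              n_dyads = n_dyads, n_images = n_images,
              cm_offsets = rep_len(cm_offsets, n_clusters),
              freq_patient_sd = freq_patient_sd,
              transfer_link = transfer_link,
              glycan_shift = glycan_shift,
              trajectory_coeffs = trajectory_coeffs,
              noise_sd = noise_sd, ga_range = ga_range)
  class(cfg) <- "sim_config"
  cfg
}

#' Cubic trajectory coefficients with a planted peak
#'
#' Builds coefficients of a cubic in gestational-age weeks whose maximum
#' over \code{ga_range} sits at \code{peak} with value \code{value_at_peak}
#' and whose amplitude over the range is \code{amplitude}; the second
#' stationary point is placed above the range so only one interior maximum
#' exists.
#'
#' @param peak Peak gestational age (weeks); an endpoint plants a monotone
#'   trajectory.
#' @param value_at_peak Frequency (percent) at the peak.
#' @param amplitude Range of the trajectory over \code{ga_range} (percent).
#' @param ga_range Gestational-age interval.
#' @return Numeric cubic coefficients (intercept, linear, quadratic, cubic).
#' @export
cubic_trajectory <- function(peak, value_at_peak, amplitude, ga_range = c(9, 41)) {
  r2 <- max(peak, ga_range[2]) + 25
  B <- function(g) g^3 / 3 - (peak + r2) / 2 * g^2 + peak * r2 * g
  lo <- ga_range[1]; hi <- ga_range[2]
  top <- if (peak >= hi) hi else if (peak <= lo) lo else peak
  a0 <- B(top) - min(B(lo), B(hi))
  k <- if (a0 > 0) amplitude / a0 else 0
  b <- k * c(0, peak * r2, -(peak + r2) / 2, 1 / 3)
  b[1] <- value_at_peak - (b[2] * top + b[3] * top^2 + b[4] * top^3)
  b
}

eval_cubic <- function(coeffs, g) {
  coeffs[1] + coeffs[2] * g + coeffs[3] * g^2 + coeffs[4] * g^3
}

# GA sampled uniformly within trimester strata with weights mirroring the
# cohort's unbalanced design (more third-trimester deliveries).
sample_ga <- function(n, ga_range, weights = c(0.25, 0.3, 0.45)) {
  bounds <- rbind(c(ga_range[1], min(14, ga_range[2])),
                  c(max(14, ga_range[1]), min(28, ga_range[2])),
                  c(max(28, ga_range[1]), ga_range[2]))
  valid <- bounds[, 1] < bounds[, 2]
  w <- weights * valid; w <- w / sum(w)
  tri <- sample.int(3, n, replace = TRUE, prob = w)
  stats::runif(n, bounds[tri, 1], bounds[tri, 2])
}

#' Generate a clinical covariate table with planted clusters
#'
#' Continuous covariates (maternal age, gravidity, pregravid BMI, EPDS,
#' CRP) are drawn from cluster-specific multivariate normals on the log
#' scale — each cluster shifting its own feature by
#' \code{cluster_effect_sd} within-cluster standard deviations — then
#' exponentiated; EPDS is rounded to non-negative integers. Cluster 1 is
#' entirely of minority ethnicity (the clinical profile the clustering
#' recovers) and fetal sex is uninformative. Gestational age is sampled by
#' trimester strata and carried as metadata.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{table} (data.frame) and \code{labels} (planted
#'   cluster per patient).
#' @export
generate_clinical_clusters <- function(config) {
  K <- config$n_clusters
  n_per <- config$n_patients_per_cluster
  if (K * n_per < 6) stop_config("n_patients_per_cluster",
                                 "need at least 6 patients in total")
  set.seed(split_seed(config$seed, "clinical"))
  # cluster offsets land on the first n_clusters features; keep those
  # continuous (integer-rounded scores would blunt the planted separation)
  feats <- c(maternal_age = log(30), pregravid_bmi = log(25), crp = log(2),
             epds = log(8), gravidity = log(2))
  log_sd <- c(maternal_age = 0.12, pregravid_bmi = 0.15, crp = 0.6,
              epds = 0.45, gravidity = 0.35)
  p <- length(feats)
  if (K > p) stop_config("n_clusters", "more clusters than continuous features")
  # each cluster shifts its own feature by cluster_effect_sd (in units of
  # that feature's within-cluster sd), mirroring the per-feature effect
  # convention used for the other planted fixtures
  centers_z <- diag(K) * config$cluster_effect_sd
  centers_z <- scale(centers_z, scale = FALSE)  # center the design
  centers_z <- cbind(centers_z, matrix(0, K, p - K))
  labels <- rep(seq_len(K), each = n_per)
  n <- length(labels)
  z <- matrix(stats::rnorm(n * p), n, p) + centers_z[labels, , drop = FALSE]
  logx <- sweep(sweep(z, 2, log_sd, "*"), 2, feats, "+")
  x <- exp(logx)
  colnames(x) <- names(feats)
  tab <- as.data.frame(x)
  tab$epds <- pmax(0L, as.integer(round(tab$epds)))
  tab$gravidity <- pmax(1L, as.integer(round(tab$gravidity)))
  # cluster 1 is entirely non-Hispanic minority (the profile the study
  # describes); the remaining clusters are mostly not
  minority_p <- c(1.0, rep(0.15, K - 1))[labels]
  tab$ethnicity <- ifelse(stats::runif(n) < minority_p,
                          "non_hispanic_minority", "other")
  tab$fetal_sex <- sample(c("F", "M"), n, replace = TRUE)
  tab$gestational_age_weeks <- sample_ga(n, config$ga_range)
  tab <- cbind(patient_id = sprintf("P%03d", seq_len(n)), tab,
               stringsAsFactors = FALSE)
  list(table = tab, labels = labels)
}

#' Generate dyadic serology with cluster-dependent transfer
#'
#' Maternal IgG subclass concentrations are log-normal; cord concentration
#' is maternal times \code{10^(cluster offset + noise)} so the planted
#' log10 cord:maternal offsets are recovered by \code{\link{cm_ratio}}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param labels Cluster labels, one per patient.
#' @param receptor_dev Optional patients x tracks matrix of standardized
#'   receptor-frequency deviations (from
#'   \code{\link{generate_area_tables}}); combined with
#'   \code{config$transfer_link} it plants a receptor-transfer partial
#'   correlation given gestational age.
#' @return List: \code{maternal}, \code{cord} (data.frames keyed by
#'   patient_id with IgG1..IgG4 columns).
#' @export
generate_serology <- function(config, labels, receptor_dev = NULL) {
  n <- length(labels)
  set.seed(split_seed(config$seed, "serology"))
  subclasses <- c(IgG1 = 5000, IgG2 = 3000, IgG3 = 500, IgG4 = 300)
  ids <- sprintf("P%03d", seq_len(n))
  maternal <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  cord <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  offs <- config$cm_offsets[labels]
  if (!is.null(receptor_dev) && length(config$transfer_link) > 0) {
    tracks <- intersect(names(config$transfer_link), colnames(receptor_dev))
    if (length(tracks) > 0) {
      offs <- offs + as.numeric(receptor_dev[, tracks, drop = FALSE] %*%
                                  config$transfer_link[tracks])
    }
  }
  for (s in names(subclasses)) {
    m <- exp(stats::rnorm(n, log(subclasses[[s]]), 0.3))
    shift <- offs + stats::rnorm(n, 0, config$noise_sd[["serology"]])
    maternal[[s]] <- m
    cord[[s]] <- m * 10^shift
  }
  list(maternal = maternal, cord = cord)
}

#' Generate maternal and cord glycoform compositions
#'
#' Maternal compositions per (dyad, subclass cluster) are drawn from a
#' Dirichlet on the registry codes; cord compositions perturb the maternal
#' log-odds by the planted \code{glycan_shift} (plus noise) and renormalize
#' to 100%.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Data.frame keyed by (patient_id, compartment, subclass) with one
#'   column per registry code; rows sum to 100.
#' @export
generate_glycoforms <- function(config) {
  set.seed(split_seed(config$seed, "glycoforms"))
  reg <- glycoform_registry()
  codes <- reg$code
  # realistic base composition: fucosylated agalacto/monogalacto dominate
  base <- stats::setNames(rep(0.5, length(codes)), codes)
  base[c("G0F", "G1F", "G2F", "G0", "G1", "NG", "G1FS", "G2FS")] <-
    c(30, 28, 12, 5, 4, 4, 6, 5)
  base <- base / sum(base)
  shift <- stats::setNames(rep(0, length(codes)), codes)
  shift[names(config$glycan_shift)] <- config$glycan_shift
  subclasses <- c("IgG1", "IgG2/3", "IgG3/4")
  rows <- list()
  for (d in seq_len(config$n_dyads)) {
    pid <- sprintf("D%03d", d)
    for (s in subclasses) {
      gm <- stats::rgamma(length(codes), shape = base * 200)
      m <- stats::setNames(gm / sum(gm), codes)
      lo <- log(m) + shift +
        stats::rnorm(length(codes), 0, config$noise_sd[["glycoforms"]])
      cvec <- exp(lo) / sum(exp(lo))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, compartment = "maternal", subclass = s,
        t(m * 100), stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, compartment = "cord", subclass = s,
        t(cvec * 100), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:3)] <- codes
  rownames(out) <- NULL
  out
}

#' Generate per-image area and cell-density tables
#'
#' For each patient the true expression frequency of each
#' (cell type, receptor) is the planted cubic evaluated at the patient's
#' gestational age, clipped to [0, 100]. Per image, marker areas (CGA,
#' CD34) are positive log-normals; intersection area = marker area x
#' frequency/100 + Gaussian noise, clipped to [0, marker area]. Pair
#' intersections are a fraction of the smaller single intersection so
#' double-positive areas never exceed either parent. HBC (CD163) tables
#' are produced as cell densities with the same construction.
#'
#' @param config A \code{\link{sim_config}}.
#' @param meta Optional data.frame (patient_id, gestational_age_weeks);
#'   generated if absent.
#' @param receptor_pairs List of receptor pairs to colocalize (default
#'   FcRn-FcgRIIIa and FcRn-FcgRIIb).
#' @return List: \code{areas} (per-image table), \code{meta},
#'   \code{true_frequency} (patient x feature matrix of planted values).
#' @export
generate_area_tables <- function(config, meta = NULL,
                                 receptor_pairs = list(c("FcRn", "FcgRIIIa"),
                                                       c("FcRn", "FcgRIIb"))) {
  set.seed(split_seed(config$seed, "areas"))
  n <- config$n_clusters * config$n_patients_per_cluster
  if (is.null(meta)) {
    meta <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                       gestational_age_weeks = sample_ga(n, config$ga_range),
                       stringsAsFactors = FALSE)
  }
  n <- nrow(meta)
  tracks <- names(config$trajectory_coeffs)
  grid <- seq(config$ga_range[1], config$ga_range[2], length.out = 101)
  # standardized patient-level deviation around the cubic; this is the
  # biological variation that transfer_link couples into the serology
  dev_z <- matrix(stats::rnorm(n * length(tracks)), n, length(tracks),
                  dimnames = list(meta$patient_id, tracks))
  truef <- sapply(tracks, function(tr) {
    cf <- config$trajectory_coeffs[[tr]]
    if (all(eval_cubic(cf, grid) < 0 | eval_cubic(cf, grid) > 100)) {
      warning(sprintf("trajectory '%s' outside [0,100] over the whole range; clipped", tr))
    }
    pmin(100, pmax(0, eval_cubic(cf, meta$gestational_age_weeks) +
                     config$freq_patient_sd * dev_z[, tr]))
  })
  rownames(truef) <- meta$patient_id
  sd_a <- config$noise_sd[["areas"]]
  overlap <- 0.6
  rows <- list()
  for (i in seq_len(n)) {
    for (img in seq_len(config$n_images)) {
      row <- list(patient_id = meta$patient_id[i],
                  image_id = sprintf("%s_img%02d", meta$patient_id[i], img),
                  villous = TRUE)
      for (marker in c("CGA", "CD34")) {
        ct <- if (marker == "CGA") "STB" else "EC"
        area <- exp(stats::rnorm(1, log(1.0), 0.2))
        row[[paste0(marker, "_area")]] <- area
        singles <- list()
        for (r in c("FcRn", "FcgRIIIa", "FcgRIIb")) {
          f <- truef[i, paste0(ct, "_", r)]
          a <- area * f / 100 + stats::rnorm(1, 0, sd_a * area)
          a <- min(area, max(0, a))
          singles[[r]] <- a
          row[[paste0(marker, "_", r, "_area")]] <- a
        }
        for (pr in receptor_pairs) {
          cap <- min(singles[[pr[1]]], singles[[pr[2]]])
          a <- overlap * cap + stats::rnorm(1, 0, sd_a * area)
          row[[paste0(marker, "_", pr[1], "_", pr[2], "_area")]] <-
            min(cap, max(0, a))
        }
      }
      dens <- exp(stats::rnorm(1, log(300), 0.2))
      row[["CD163_density"]] <- dens
      for (r in c("FcRn", "FcgRIIIa", "FcgRIIb")) {
        f <- truef[i, paste0("HBC_", r)]
        d <- dens * f / 100 + stats::rnorm(1, 0, sd_a * dens)
        row[[paste0("CD163_", r, "_density")]] <- min(dens, max(0, d))
      }
      rows[[length(rows) + 1]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  areas <- do.call(rbind, rows)
  rownames(areas) <- NULL
  list(areas = areas, meta = meta, true_frequency = truef,
       patient_dev = dev_z)
}

#' Generate 5PL standard-curve data
#'
#' Responses are the 5PL evaluated at the standard concentrations plus
#' Gaussian noise scaled to the curve's dynamic range; unknowns are emitted
#' alongside with their true concentrations.
#'
#' @param params Named list with 5PL parameters a, d, c, b, g (c > 0).
#' @param concentrations Standard concentrations (> 0).
#' @param noise_sd Noise as a fraction of the response range.
#' @param seed RNG seed.
#' @param unknowns True concentrations of unknown samples (optional).
#' @return List: \code{standards} (concentration, response),
#'   \code{unknowns} (true_concentration, response).
#' @export
generate_standard_curves <- function(params, concentrations, noise_sd, seed,
                                     unknowns = NULL) {
  if (params$c <= 0) stop_config("c", "5PL inflection scale must be positive")
  if (any(concentrations <= 0)) stop_config("concentrations", "must be positive")
  set.seed(seed)
  rng <- abs(params$a - params$d)
  resp <- function(x) eval_5pl(x, params$a, params$d, params$c, params$b,
                               params$g) +
    stats::rnorm(length(x), 0, noise_sd * rng)
  std <- data.frame(concentration = concentrations,
                    response = resp(concentrations))
  unk <- if (is.null(unknowns)) NULL else
    data.frame(true_concentration = unknowns, response = resp(unknowns))
  list(standards = std, unknowns = unk)
}

#' Generate the complete synthetic bundle
#'
#' Runs every generator under one configuration and returns all table
#' families plus the planted ground truth.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{sim_bundle}: clinical, labels, serology
#'   (maternal/cord), glycoforms, areas (with meta and true frequencies),
#'   and \code{truth} covering every planted parameter.
#' @export
generate_bundle <- function(config = sim_config()) {
  clin <- generate_clinical_clusters(config)
  ar <- generate_area_tables(config, meta = clin$table[, c("patient_id",
                                                           "gestational_age_weeks")])
  sero <- generate_serology(config, clin$labels, receptor_dev = ar$patient_dev)
  gly <- generate_glycoforms(config)
  structure(list(
    clinical = clin$table, labels = clin$labels,
    serology = sero, glycoforms = gly, areas = ar,
    truth = list(labels = clin$labels,
                 cm_offsets = config$cm_offsets,
                 transfer_link = config$transfer_link,
                 patient_dev = ar$patient_dev,
                 glycan_shift = config$glycan_shift,
                 trajectory_coeffs = config$trajectory_coeffs,
                 true_frequency = ar$true_frequency,
                 config = config)),
    class = "sim_bundle")
}
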