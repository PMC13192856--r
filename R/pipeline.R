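# Orchestration: the end-to-end analysis over a bundle of input tables,
# and schema/invariant validation of the table families.

#' Run the full multimodal analysis
#'
#' Executes the stages in study order on a (typically synthetic) bundle:
#' image quantification, transfer metrics, glycoform summaries,
#' clinical clustering with second-cohort projection, trimester PLSDA with
#' permutation testing, gestational-age OPLSR with Q2, LASSO stability
#' selection on the maternal/cord glycoform contrast, partial-correlation
#' networks, and cubic/exponential trends. Writes tables (TSV), model
#' summaries (JSON), networks (GraphML) and a run manifest under
#' \code{output_dir}; returns the results invisibly-ish as a list.
#'
#' @param bundle A \code{sim_bundle} (cohort 1).
#' @param bundle2 Optional second cohort bundle; generated from the same
#'   configuration with a shifted seed when absent.
#' @param output_dir Output directory, or \code{NULL} to skip writing.
#' @param rounds Cross-validation/permutation rounds (study design: 1000).
#' @param lasso_iterations Stability-selection iterations.
#' @param seed Root seed for the stochastic stages.
#' @return List with one element per stage plus a \code{manifest}.
#' @export
run_full_analysis <- function(bundle, bundle2 = NULL, output_dir = NULL,
                              rounds = 100, lasso_iterations = 200, seed = 1) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (is.null(bundle2)) {
    cfg2 <- bundle$truth$config
    cfg2$seed <- split_seed(cfg2$seed, "cohort2")
    bundle2 <- generate_bundle(cfg2)
  }
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  # 1. quantify: per-patient expression profiles
  profile <- run_stage("quantify", build_expression_profile(
    bundle$areas$areas, bundle$areas$meta))
  profile2 <- build_expression_profile(bundle2$areas$areas, bundle2$areas$meta)

  # 2. transfer metrics + glycoform summaries
  transfer <- run_stage("transfer", cm_ratio(bundle$serology$maternal,
                                             bundle$serology$cord))
  summaries <- run_stage("glycans", summary_glycans(bundle$glycoforms))
  enrichment <- paired_enrichment(summaries)

  # 3. clinical clustering + cohort-2 projection
  clin_feats <- setdiff(names(bundle$clinical), "gestational_age_weeks")
  latent <- run_stage("cluster", fit_latent_model(bundle$clinical[clin_feats],
                                                  seed = split_seed(seed, "kmeans")))
  proj <- project_cohort(latent, bundle2$clinical[clin_feats])
  assigned <- assign_clusters(proj[, 1:2, drop = FALSE], latent)

  # 4. PLS models: trimester PLSDA and gestational-age OPLSR
  feat_cols <- setdiff(names(profile),
                       c("patient_id", "gestational_age_weeks", "trimester"))
  X <- as.matrix(profile[feat_cols])
  plsda <- run_stage("plsda", {
    m <- fit_plsda(X, factor(profile$trimester), n_components = 2)
    perm <- permutation_test(X, factor(profile$trimester), rounds = rounds,
                             seed = split_seed(seed, "plsda"))
    list(model = orthogonalize(m), vip = NULL, permutation = perm)
  })
  plsda$vip <- vip_scores(plsda$model)
  oplsr <- run_stage("oplsr", {
    m <- orthogonalize(fit_pls(X, profile$gestational_age_weeks,
                               n_components = 2))
    q2 <- q2_score(X, profile$gestational_age_weeks,
                   seed = split_seed(seed, "q2"))
    pred2 <- predict(m, as.matrix(profile2[feat_cols]))
    r <- stats::cor(pred2[, 1], profile2$gestational_age_weeks)
    slope <- unname(stats::coef(stats::lm(
      profile2$gestational_age_weeks ~ pred2[, 1]))[2])
    list(model = m, q2 = q2, cohort2_r = r, cohort2_slope = slope,
         vip = vip_scores(m))
  })

  # 5. LASSO stability selection on maternal vs cord glycoforms
  stab <- run_stage("lasso", {
    gw <- bundle$glycoforms
    codes <- setdiff(names(gw), c("patient_id", "compartment", "subclass"))
    wide <- stats::reshape(gw, direction = "wide", idvar = c("patient_id", "compartment"),
                           timevar = "subclass", v.names = codes)
    Xg <- as.matrix(wide[, setdiff(names(wide), c("patient_id", "compartment"))])
    sel <- stability_select(Xg, wide$compartment,
                            n_iterations = lasso_iterations,
                            seed = split_seed(seed, "lasso"))
    net <- if (length(sel$selected) > 0)
      cocorrelate_network(Xg, sel$selected) else NULL
    list(selection = sel, network = net, labels = wide$compartment, X = Xg)
  })

  # 6. partial-correlation network: receptor expression vs transfer
  pcn <- run_stage("pcn", {
    twide <- stats::reshape(transfer, direction = "wide", idvar = "patient_id",
                            timevar = "feature")
    names(twide) <- sub("^log10_cm\\.", "CM_", names(twide))
    covs <- bundle$clinical[c("patient_id", "gestational_age_weeks",
                              "maternal_age", "gravidity", "pregravid_bmi",
                              "epds")]
    build_pcn(profile[c("patient_id", feat_cols)], twide, covs)
  })

  # 7. trends: cubic receptor trajectories and exponential cord IgG
  trends <- run_stage("trends", {
    cubics <- lapply(feat_cols, function(f) {
      fit_cubic(profile$gestational_age_weeks, profile[[f]])
    })
    names(cubics) <- feat_cols
    t3 <- bundle$clinical$gestational_age_weeks >= 28
    ids3 <- bundle$clinical$patient_id[t3]
    crd <- bundle$serology$cord
    crd3 <- crd[crd$patient_id %in% ids3, ]
    ga3 <- bundle$clinical$gestational_age_weeks[
      match(crd3$patient_id, bundle$clinical$patient_id)]
    expfits <- lapply(c("IgG1", "IgG2", "IgG3", "IgG4"), function(s) {
      fit_exponential(ga3, crd3[[s]])
    })
    names(expfits) <- c("IgG1", "IgG2", "IgG3", "IgG4")
    list(cubic = cubics, exponential = expfits)
  })

  manifest <- list(stages = stages, seed = seed, rounds = rounds,
                   lasso_iterations = lasso_iterations,
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  results <- list(profile = profile, profile2 = profile2,
                  transfer = transfer, glycan_summaries = summaries,
                  glycan_enrichment = enrichment,
                  latent = latent, cohort2_scores = proj,
                  cohort2_assignment = assigned,
                  plsda = plsda, oplsr = oplsr, stability = stab,
                  pcn = pcn, trends = trends, manifest = manifest)
  if (!is.null(output_dir)) write_results(results, output_dir)
  results
}

write_results <- function(results, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(output_dir, name), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wt(results$profile, "expression_profile_cohort1.tsv")
  wt(results$profile2, "expression_profile_cohort2.tsv")
  wt(results$transfer, "transfer_ratios.tsv")
  wt(results$glycan_summaries, "glycan_summaries.tsv")
  wt(results$glycan_enrichment, "glycan_enrichment.tsv")
  wt(data.frame(patient_id = rownames(results$latent$scores),
                results$latent$scores[, 1:2],
                cluster = results$latent$labels),
     "cluster_scores_cohort1.tsv")
  wt(data.frame(patient_id = rownames(results$cohort2_scores),
                results$cohort2_scores[, 1:2],
                cluster = results$cohort2_assignment),
     "cluster_scores_cohort2.tsv")
  jsonlite::write_json(list(
    plsda = list(mean_cv_accuracy = results$plsda$permutation$mean_statistic,
                 permutation_p = results$plsda$permutation$p_value,
                 vip = as.list(results$plsda$vip)),
    oplsr = list(q2 = results$oplsr$q2,
                 cohort2_pearson_r = results$oplsr$cohort2_r,
                 cohort2_slope = results$oplsr$cohort2_slope,
                 vip = as.list(results$oplsr$vip)),
    stability = list(frequency = as.list(results$stability$selection$frequency),
                     selected = results$stability$selection$selected),
    peaks = lapply(results$trends$cubic, function(f) f$peak_ga),
    manifest = results$manifest),
    file.path(output_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  if (nrow(results$pcn$edges) > 0) {
    write_network(results$pcn,
                  graphml = file.path(output_dir, "pcn.graphml"),
                  edgelist = file.path(output_dir, "pcn_edges.csv"))
  }
  if (!is.null(results$stability$network)) {
    write_network(results$stability$network,
                  graphml = file.path(output_dir, "cocorrelate.graphml"),
                  edgelist = file.path(output_dir, "cocorrelate_edges.csv"))
  }
  invisible(output_dir)
}

#' Validate input table families
#'
#' Schema and invariant checks: compositions on the 100% simplex,
#' non-negative areas, intersections bounded by parents, dyad matching.
#'
#' @param bundle A \code{sim_bundle} (or list with the same elements).
#' @return Data.frame of violations (table, row, check); zero rows when
#'   everything is clean.
#' @export
validate_tables <- function(bundle) {
  v <- list()
  add <- function(table, row, check) {
    v[[length(v) + 1]] <<- data.frame(table = table, row = row, check = check,
                                      stringsAsFactors = FALSE)
  }
  # glycoform simplex
  gly <- bundle$glycoforms
  if (!is.null(gly)) {
    codes <- setdiff(names(gly), c("patient_id", "compartment", "subclass"))
    sums <- rowSums(gly[codes])
    for (i in which(abs(sums - 100) > 1e-6)) {
      add("glycoforms", i, sprintf("composition sums to %.6f, not 100", sums[i]))
    }
  }
  # area bounds
  ar <- bundle$areas$areas
  if (!is.null(ar)) {
    acols <- grep("_area$|_density$", names(ar), value = TRUE)
    for (cl in acols) {
      for (i in which(ar[[cl]] < 0)) add("areas", i, sprintf("%s negative", cl))
    }
    for (marker in c("CGA", "CD34")) {
      parent <- paste0(marker, "_area")
      kids <- setdiff(grep(paste0("^", marker, "_.*_area$"), names(ar),
                           value = TRUE), parent)
      for (cl in kids) {
        for (i in which(ar[[cl]] > ar[[parent]] + 1e-9)) {
          add("areas", i, sprintf("%s exceeds %s", cl, parent))
        }
      }
    }
  }
  # dyad matching
  if (!is.null(bundle$serology)) {
    m <- bundle$serology$maternal$patient_id
    c_ <- bundle$serology$cord$patient_id
    for (id in setdiff(c_, m)) add("serology", NA, sprintf("cord sample %s lacks maternal mate", id))
    for (id in setdiff(m, c_)) add("serology", NA, sprintf("maternal sample %s lacks cord mate", id))
  }
  # clinical hub: every patient id elsewhere appears in clinical
  if (!is.null(bundle$clinical) && !is.null(ar)) {
    for (id in setdiff(unique(ar$patient_id), bundle$clinical$patient_id)) {
      add("areas", NA, sprintf("patient %s missing from clinical table", id))
    }
  }
  if (length(v) == 0) {
    return(data.frame(table = character(0), row = integer(0),
                      check = character(0)))
  }
  do.call(rbind, v)
}
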