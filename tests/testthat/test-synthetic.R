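# Generator contracts: determinism, planted effects, simplex/area bounds,
# zero-noise round trips.

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 42, n_patients_per_cluster = 5)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$serology, b2$serology)
  expect_identical(b1$glycoforms, b2$glycoforms)
  expect_identical(b1$areas$areas, b2$areas$areas)
})

test_that("invalid configurations fail naming the field", {
  expect_error(sim_config(n_clusters = 0), "n_clusters")
  expect_error(sim_config(noise_sd = c(clinical = -1)), "noise_sd")
  expect_error(sim_config(ga_range = c(2, 41)), "ga_range")
  expect_error(sim_config(glycan_shift = c(BOGUS = 1)), "BOGUS")
  expect_error(generate_clinical_clusters(
    sim_config(n_patients_per_cluster = 1, n_clusters = 2)),
    "n_patients_per_cluster")
})

test_that("zero cluster effect gives no recoverable structure", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(seed = 8, cluster_effect_sd = 0)
  cl <- generate_clinical_clusters(cfg)
  tab <- cl$table[, setdiff(names(cl$table), "gestational_age_weeks")]
  m <- fit_latent_model(tab, k = 3, seed = 1)
  expect_lt(abs(mclust::adjustedRandIndex(m$labels, cl$labels)), 0.15)
})

test_that("serology planting: zero offsets give zero log ratios, planted offsets separate clusters", {
  cfg0 <- sim_config(seed = 5, cm_offsets = c(0, 0, 0),
                     noise_sd = c(clinical = 1, serology = 0, glycoforms = 0.1,
                                  areas = 0.03, mfi = 0.02))
  cl <- generate_clinical_clusters(cfg0)
  s <- generate_serology(cfg0, cl$labels)
  tr <- cm_ratio(s$maternal, s$cord)
  expect_true(all(abs(tr$log10_cm) < 1e-12))
  expect_true(all(s$maternal[-1] > 0) && all(s$cord[-1] > 0))

  cfg <- sim_config(seed = 5, cm_offsets = c(0.3, 0, -0.3),
                    noise_sd = c(clinical = 1, serology = 0.05,
                                 glycoforms = 0.1, areas = 0.03, mfi = 0.02))
  cl <- generate_clinical_clusters(cfg)
  s <- generate_serology(cfg, cl$labels)
  tr <- cm_ratio(s$maternal, s$cord)
  igg1 <- tr[tr$feature == "IgG1", ]
  lab <- cl$labels[match(igg1$patient_id, cl$table$patient_id)]
  p <- stats::wilcox.test(igg1$log10_cm[lab == 1], igg1$log10_cm[lab == 3])$p.value
  expect_lt(p, 0.01)
})

test_that("glycoform compositions sit on the simplex and zero shift reproduces maternal", {
  cfg <- sim_config(seed = 3, n_dyads = 6,
                    glycan_shift = c(G0F = 0),
                    noise_sd = c(clinical = 1, serology = 0.05,
                                 glycoforms = 0, areas = 0.03, mfi = 0.02))
  gf <- generate_glycoforms(cfg)
  codes <- setdiff(names(gf), c("patient_id", "compartment", "subclass"))
  expect_true(all(abs(rowSums(gf[codes]) - 100) < 1e-9))
  m <- gf[gf$compartment == "maternal", codes]
  c_ <- gf[gf$compartment == "cord", codes]
  expect_equal(as.matrix(m), as.matrix(c_), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("planted sialylation shift is detected by the paired signed-rank screen", {
  reg <- glycoform_registry()
  s_codes <- reg$code[reg$sialylated]
  cfg <- sim_config(seed = 21, n_dyads = 14,
                    glycan_shift = stats::setNames(rep(0.5, length(s_codes)),
                                                   s_codes))
  gf <- generate_glycoforms(cfg)
  pe <- paired_enrichment(summary_glycans(gf))
  sial <- pe[pe$feature == "sialylated", ]
  expect_lt(sial$p_value, 0.05)
  expect_gt(sial$median_diff, 0)
})

test_that("area tables respect bounds and round-trip exactly at zero noise", {
  cfg <- sim_config(seed = 2, n_patients_per_cluster = 5,
                    noise_sd = c(clinical = 1, serology = 0, glycoforms = 0,
                                 areas = 0, mfi = 0))
  at <- generate_area_tables(cfg)
  ar <- at$areas
  for (marker in c("CGA", "CD34")) {
    parent <- ar[[paste0(marker, "_area")]]
    kids <- setdiff(grep(paste0("^", marker, "_.*_area$"), names(ar),
                         value = TRUE), paste0(marker, "_area"))
    for (k in kids) expect_true(all(ar[[k]] <= parent + 1e-12))
  }
  # pair intersections bounded by both singles
  expect_true(all(ar$CGA_FcRn_FcgRIIIa_area <= pmin(ar$CGA_FcRn_area,
                                                    ar$CGA_FcgRIIIa_area) + 1e-12))
  prof <- build_expression_profile(ar, at$meta)
  got <- as.matrix(prof[colnames(at$true_frequency)])
  expect_equal(unname(got), unname(at$true_frequency), tolerance = 1e-10)
})

test_that("standard-curve generator honors the 5PL midpoint identity", {
  p <- list(a = 100, d = 20000, c = 500, b = 2, g = 1)
  sim <- generate_standard_curves(p, rep(p$c, 3), noise_sd = 0, seed = 1)
  expect_equal(sim$standards$response,
               rep(p$d + (p$a - p$d) / 2, 3), tolerance = 1e-12)
  expect_error(generate_standard_curves(list(a = 1, d = 2, c = -1, b = 1, g = 1),
                                        c(1, 2), 0, 1), "'c'")
})
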