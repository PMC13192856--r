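# 5PL standard curves, transfer ratios, glycoform summaries and screens.

test_that("glycoform registry parses motif flags and rejects unknown codes", {
  reg <- glycoform_registry()
  expect_true(all(!duplicated(reg$code)))
  g2fs <- reg[reg$code == "G2FS", ]
  expect_equal(g2fs$galactose_count, 2L)
  expect_true(g2fs$fucosylated && g2fs$sialylated && !g2fs$bisected)
  expect_true(reg[reg$code == "NG", "non_glycosylated"])
  expect_error(parse_glycoform_code("G3FX"), "unknown")
  expect_error(check_glycoform_codes("Z9"), "Z9")
})

test_that("noiseless 5PL data are fit and inverted to machine precision", {
  p <- ref_5pl()
  conc <- ref_5pl_standards()
  y <- eval_5pl(conc, p$a, p$d, p$c, p$b, p$g)
  cur <- fit_5pl(conc, y)
  # midpoint identity at x = c for g = 1
  expect_equal(eval_5pl(p$c, cur$a, cur$d, cur$c, cur$b, cur$g),
               (p$a + p$d) / 2, tolerance = 1e-6)
  # invert-then-evaluate round trip on the fitted curve
  x0 <- c(30, 200, 1500)
  y0 <- eval_5pl(x0, cur$a, cur$d, cur$c, cur$b, cur$g)
  expect_equal(invert_5pl(cur, y0)$concentration, x0, tolerance = 1e-10)
})

test_that("a 4PL-constrained fit recovers 4PL data", {
  conc <- ref_5pl_standards()
  y <- eval_5pl(conc, 100, 25000, 300, 1.5, 1)
  cur <- fit_5pl(conc, y, fix_g = 1)
  expect_equal(cur$g, 1)
  expect_equal(cur$c, 300, tolerance = 1e-4)
  expect_equal(cur$b, 1.5, tolerance = 1e-4)
})

test_that("5PL inversion applies dilution and flags out-of-range responses", {
  p <- ref_5pl()
  conc <- ref_5pl_standards()
  cur <- fit_5pl(conc, eval_5pl(conc, p$a, p$d, p$c, p$b, p$g))
  y_mid <- eval_5pl(2, cur$a, cur$d, cur$c, cur$b, cur$g)
  out <- invert_5pl(cur, y_mid, dilution = 15000)
  expect_equal(out$concentration, 30000, tolerance = 1e-6)
  oob <- invert_5pl(cur, c(cur$a - 1, cur$d + 1))
  expect_false(any(oob$in_range))
  expect_true(all(is.na(oob$concentration)))
  expect_error(fit_5pl(c(1, 2, 3), c(1, 2, 3)), "at least 6")
})

test_that("cm_ratio computes log10 cord:maternal and is antisymmetric", {
  m <- data.frame(patient_id = c("a", "b", "c"), IgG1 = c(10, 10, 50))
  c_ <- data.frame(patient_id = c("a", "b", "c"), IgG1 = c(10, 100, 5))
  tr <- cm_ratio(m, c_)
  expect_equal(tr$log10_cm, c(0, 1, -1), tolerance = 1e-12)
  rev_ <- cm_ratio(c_, m)
  expect_equal(rev_$log10_cm, -tr$log10_cm, tolerance = 1e-12)
  # unmatched and non-positive handling
  m2 <- rbind(m, data.frame(patient_id = "d", IgG1 = 5))
  c2 <- c_; c2$IgG1[1] <- 0
  expect_warning(tr2 <- cm_ratio(m2, c2), "excluded")
  expect_equal(attr(tr2, "unmatched"), "d")
  expect_equal(attr(tr2, "n_excluded"), 1L)
})

test_that("summary glycans sum motif abundances with NG excluded", {
  prof <- data.frame(patient_id = "p", compartment = "maternal",
                     subclass = "IgG1", G0F = 100)
  s <- summary_glycans(prof)
  expect_equal(s$fucosylated, 100)
  expect_equal(s$agalactosylated, 100)
  expect_equal(s$sialylated, 0)
  prof2 <- data.frame(patient_id = "p", compartment = "cord",
                      subclass = "IgG1", G2FS = 50, G0 = 50)
  s2 <- summary_glycans(prof2)
  expect_equal(s2$sialylated, 50)
  expect_equal(s2$digalactosylated, 50)
  expect_equal(s2$fucosylated, 50)
  expect_equal(s2$agalactosylated, 50)
  # no bisected code present -> bisection 0; NG carries no motif
  prof3 <- data.frame(patient_id = "p", compartment = "cord",
                      subclass = "IgG1", NG = 40, G1F = 60)
  s3 <- summary_glycans(prof3)
  expect_equal(s3$bisected, 0)
  expect_equal(s3$monogalactosylated, 60)
  expect_error(summary_glycans(data.frame(patient_id = "p", BAD = 1)), "BAD")
})

test_that("summary motifs are invariant to uniform rescaling after renormalization", {
  set.seed(4)
  reg <- glycoform_registry()
  ab <- stats::runif(nrow(reg)); ab <- ab / sum(ab) * 100
  prof <- cbind(data.frame(patient_id = "p", compartment = "m", subclass = "IgG1"),
                as.data.frame(as.list(stats::setNames(ab, reg$code))))
  prof_scaled <- prof
  prof_scaled[reg$code] <- prof[reg$code] * 3 / sum(prof[reg$code] * 3) * 100
  expect_equal(summary_glycans(prof)[-(1:3)],
               summary_glycans(prof_scaled)[-(1:3)], tolerance = 1e-12)
})

test_that("paired enrichment flags all-tie features and enforces minimum dyads", {
  wide <- data.frame(patient_id = rep(paste0("d", 1:6), 2),
                     compartment = rep(c("maternal", "cord"), each = 6),
                     sialylated = rep(10, 12))
  pe <- paired_enrichment(wide)
  expect_true(pe$all_ties)
  expect_equal(pe$p_value, 1)
  wide4 <- wide[wide$patient_id %in% paste0("d", 1:4), ]
  expect_error(paired_enrichment(wide4), "dyads")
})

test_that("covariate-glycan screen returns exact rank correlations and masks degenerate pairs", {
  clin <- data.frame(patient_id = paste0("p", 1:10), bmi = 1:10,
                     crp = rep(3, 10))
  gly <- data.frame(patient_id = paste0("p", 1:10),
                    sialylated = (1:10)^2, fucosylated = -(1:10))
  cc <- covariate_glycan_correlations(clin, gly)
  expect_equal(cc$rho[cc$covariate == "bmi" & cc$glycan == "sialylated"], 1)
  expect_equal(cc$rho[cc$covariate == "bmi" & cc$glycan == "fucosylated"], -1)
  expect_true(all(cc$masked[cc$covariate == "crp"]))
})

test_that("null rank-correlation screen rejects at roughly the nominal rate", {
  set.seed(99)
  n <- 14; reps <- 400
  hits <- sum(replicate(reps, {
    ct <- suppressWarnings(stats::cor.test(stats::rnorm(n), stats::rnorm(n),
                                           method = "spearman", exact = FALSE))
    ct$p.value < 0.05
  }))
  rate <- hits / reps
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
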