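# Expression-frequency formulas, colocalization partitions, and receptor
# ratios from per-image tables.

test_that("area-based frequency is intersection over marker area times 100", {
  aq <- tiny_area_table("P1", 2.0, 0.5)
  expect_equal(expression_frequency_area(aq, "STB", "FcRn")$frequency, 25.0)
  # unweighted mean over images, not area-weighted
  aq2 <- tiny_area_table(c("P1", "P1"), c(1.0, 3.0), c(0.1, 0.9))
  expect_equal(expression_frequency_area(aq2, "STB", "FcRn")$frequency, 20.0)
  aq3 <- tiny_area_table("P1", 1.5, 1.5)
  expect_equal(expression_frequency_area(aq3, "STB", "FcRn")$frequency, 100.0)
})

test_that("patients with all-zero marker area are excluded with a warning", {
  aq <- tiny_area_table(c("P1", "P2"), c(0, 2), c(0, 1))
  expect_warning(out <- expression_frequency_area(aq, "STB", "FcRn"), "P1")
  expect_identical(out$patient_id, "P2")
})

test_that("cell-density frequency normalizes to total HBC density", {
  aq <- data.frame(patient_id = c("P1", "P1"), image_id = c("i1", "i2"),
                   CD163_density = c(10, 20),
                   CD163_FcRn_density = c(5, 5))
  expect_equal(expression_frequency_cells(aq, "FcRn")$frequency,
               mean(c(50, 25)))
  aq0 <- data.frame(patient_id = "P1", image_id = "i1",
                    CD163_density = 120, CD163_FcRn_density = 0)
  expect_equal(expression_frequency_cells(aq0, "FcRn")$frequency, 0.0)
})

test_that("coexpression partition follows inclusion-exclusion and closes to 100", {
  aq <- data.frame(patient_id = "P1", image_id = "i1", villous = TRUE,
                   CGA_area = 1.0, CGA_FcRn_area = 0.4,
                   CGA_FcgRIIIa_area = 0.3, CGA_FcRn_FcgRIIIa_area = 0.1)
  part <- coexpression_partition(aq, "STB", c("FcRn", "FcgRIIIa"))
  expect_equal(unlist(part[1, c("pp", "pn", "np", "nn")]),
               c(pp = 10, pn = 30, np = 20, nn = 40))
  # perfect colocalization: off-diagonal compartments vanish
  aq2 <- aq; aq2$CGA_FcgRIIIa_area <- 0.4; aq2$CGA_FcRn_FcgRIIIa_area <- 0.4
  part2 <- coexpression_partition(aq2, "STB", c("FcRn", "FcgRIIIa"))
  expect_equal(unlist(part2[1, c("pn", "np")]), c(pn = 0, np = 0))
  expect_equal(part2$pp + part2$nn, 100)
  # receptor-free tissue
  aq3 <- aq; aq3[c("CGA_FcRn_area", "CGA_FcgRIIIa_area",
                   "CGA_FcRn_FcgRIIIa_area")] <- 0
  part3 <- coexpression_partition(aq3, "STB", c("FcRn", "FcgRIIIa"))
  expect_equal(unlist(part3[1, c("pp", "pn", "np", "nn")]),
               c(pp = 0, pn = 0, np = 0, nn = 100))
  # integrity: pair exceeding a single is an error
  aq4 <- aq; aq4$CGA_FcRn_FcgRIIIa_area <- 0.35
  expect_error(coexpression_partition(aq4, "STB", c("FcRn", "FcgRIIIa")),
               "exceeds")
})

test_that("partition closure holds across random generated tables", {
  cfg <- sim_config(seed = 31, n_patients_per_cluster = 4)
  at <- generate_area_tables(cfg)
  for (ct in c("STB", "EC")) {
    part <- coexpression_partition(at$areas, ct, c("FcRn", "FcgRIIb"))
    expect_true(all(abs(rowSums(part[, c("pp", "pn", "np", "nn")]) - 100) < 1e-6))
  }
})

test_that("per-patient aggregation equals a brute-force per-image loop", {
  set.seed(77)
  n_img <- 40
  aq <- tiny_area_table(sample(paste0("P", 1:8), n_img, replace = TRUE),
                        stats::runif(n_img, 0.5, 3), 0)
  aq$CGA_FcRn_area <- aq$CGA_area * stats::runif(n_img)
  out <- expression_frequency_area(aq, "STB", "FcRn")
  brute <- sapply(out$patient_id, function(p) {
    rows <- aq[aq$patient_id == p, ]
    mean(rows$CGA_FcRn_area / rows$CGA_area * 100)
  })
  expect_equal(out$frequency, unname(brute), tolerance = 1e-12)
})

test_that("receptor ratios report log10 ratios, both group summaries, and a paired test", {
  prof <- data.frame(patient_id = paste0("P", 1:6),
                     STB_FcgRIIIa = c(10, 20, 30, 15, 25, 35),
                     STB_FcRn = c(5, 10, 15, 7.5, 12.5, 17.5))
  rr <- receptor_ratio(prof, "FcgRIIIa", "FcRn", "STB")
  expect_equal(rr$per_patient$log10_ratio, rep(log10(2), 6), tolerance = 1e-12)
  expect_equal(rr$ratio_of_means, 2)
  expect_equal(rr$mean_of_ratios, 2)
  # identical frequencies: all ties, p = 1
  prof2 <- prof; prof2$STB_FcgRIIIa <- prof2$STB_FcRn
  rr2 <- receptor_ratio(prof2, "FcgRIIIa", "FcRn", "STB")
  expect_true(all(rr2$per_patient$log10_ratio == 0))
  expect_equal(rr2$p_value, 1)
  # zero denominators excluded with warning and counted
  prof3 <- prof; prof3$STB_FcRn[2] <- 0
  expect_warning(rr3 <- receptor_ratio(prof3, "FcgRIIIa", "FcRn", "STB"), "excluded")
  expect_equal(rr3$n_excluded, 1)
})

test_that("planted group ratio is recovered from third-trimester synthetic data", {
  # frequencies with a planted FcgRIIIa/FcRn mean ratio of 0.44
  set.seed(12)
  n <- 40
  fcrn <- stats::rnorm(n, 60, 6)
  fciiia <- 0.44 * fcrn * exp(stats::rnorm(n, 0, 0.1))
  prof <- data.frame(patient_id = paste0("P", seq_len(n)),
                     STB_FcgRIIIa = fciiia, STB_FcRn = fcrn)
  rr <- receptor_ratio(prof, "FcgRIIIa", "FcRn", "STB")
  expect_gt(rr$ratio_of_means, 0.34)
  expect_lt(rr$ratio_of_means, 0.54)
  expect_lt(rr$p_value, 0.001)
})

test_that("trimester boundaries assign boundary weeks to the later trimester", {
  expect_identical(assign_trimester(c(9, 13.9, 14, 27.9, 28, 41)),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
})
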