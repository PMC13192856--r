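# Clinical preprocessing, PCA, WSS-guided k-means, and cross-cohort
# projection.

test_that("preprocessing z-scores, drops constants, and is reproducible on new data", {
  set.seed(10)
  tab <- data.frame(patient_id = paste0("p", 1:20),
                    bmi = exp(stats::rnorm(20, 3, 0.2)),
                    crp = exp(stats::rnorm(20, 0.5, 0.5)),
                    ones = rep(2, 20),
                    sex = sample(c("F", "M"), 20, replace = TRUE))
  expect_warning(pre <- preprocess_clinical(tab), "constant")
  expect_false("ones" %in% colnames(pre$x))
  expect_true(all(abs(colMeans(pre$x)) < 1e-12))
  expect_true(all(abs(apply(pre$x, 2, stats::sd) - 1) < 1e-12))
  # frozen params reproduce the training matrix exactly
  again <- apply_preprocess(tab, pre$params)
  expect_equal(again, pre$x, tolerance = 1e-12)
})

test_that("rows with incomplete observations are removed before fitting", {
  tab <- data.frame(patient_id = paste0("p", 1:6),
                    bmi = c(20, 22, NA, 24, 25, 28),
                    crp = exp(stats::rnorm(6)))
  expect_message(pre <- preprocess_clinical(tab), "incomplete")
  expect_equal(pre$removed, "p3")
  expect_equal(nrow(pre$x), 5)
})

test_that("zeros are log-handled with a half-minimum offset", {
  tab <- data.frame(patient_id = paste0("p", 1:5),
                    epds = c(0, 2, 4, 8, 16))
  pre <- preprocess_clinical(tab)
  expect_equal(pre$params$features$epds$offset, 1)
  expect_true(all(is.finite(pre$x)))
})

test_that("PCA: collinear data load on one component, scores follow the loadings", {
  x <- cbind(a = 1:10, b = 2 * (1:10))
  m <- fit_pca(scale(x))
  expect_equal(m$explained_variance[1], 1, tolerance = 1e-12)
  set.seed(2)
  xr <- matrix(stats::rnorm(60), 12, 5)
  mr <- fit_pca(xr)
  expect_equal(crossprod(mr$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  xc <- sweep(xr, 2, colMeans(xr), "-")
  expect_equal(mr$scores, xc %*% mr$loadings, tolerance = 1e-10)
  expect_true(all(diff(mr$explained_variance) < 1e-12))
})

test_that("isotropic data split variance evenly across components", {
  set.seed(5)
  m <- fit_pca(matrix(stats::rnorm(4000), 2000, 2))
  expect_equal(m$explained_variance, c(0.5, 0.5), tolerance = 0.03)
})

test_that("WSS curve starts at the total sum of squares and elbows at planted K", {
  set.seed(6)
  cen <- rbind(c(0, 0), c(6, 0), c(3, 6))
  lab <- rep(1:3, each = 40)
  s <- cen[lab, ] + matrix(stats::rnorm(240), 120, 2)
  sel <- select_k_wss(s, k_max = 6, seed = 1)
  expect_equal(sel$wss[1], sum(scale(s, scale = FALSE)^2), tolerance = 1e-9)
  expect_equal(sel$k, 3L)
  expect_false(sel$weak_elbow)
  # one blob: no strong structure
  s1 <- matrix(stats::rnorm(200), 100, 2)
  sel1 <- select_k_wss(s1, k_max = 6, seed = 1)
  expect_true(sel1$weak_elbow || sel1$k <= 2)
  expect_error(select_k_wss(s1, k_max = 1), "k_max")
})

test_that("k-means is deterministic given the seed and K=1 returns the mean", {
  set.seed(7)
  s <- matrix(stats::rnorm(100), 50, 2)
  km1 <- kmeans_cluster(s, 1, seed = 3)
  expect_equal(as.numeric(km1$centroids), colMeans(s), tolerance = 1e-12)
  a <- kmeans_cluster(s, 3, seed = 5)
  b <- kmeans_cluster(s, 3, seed = 5)
  expect_identical(a$labels, b$labels)
})

test_that("projection with training parameters reproduces training scores", {
  cfg <- sim_config(seed = 9, n_patients_per_cluster = 10)
  cl <- generate_clinical_clusters(cfg)
  tab <- cl$table[, setdiff(names(cl$table), "gestational_age_weeks")]
  m <- fit_latent_model(tab, k = 3, seed = 1)
  pr <- project_cohort(m, tab)
  expect_equal(pr, m$scores, tolerance = 1e-10)
  expect_error(project_cohort(m, tab[, 1:3]), "lacks feature")
})

test_that("centroid assignment takes the nearest centroid with low-index ties", {
  model <- list(centroids = rbind(c(0, 0), c(4, 0), c(2, 5)))
  expect_equal(assign_clusters(rbind(c(4, 0)), model), 2L)
  # equidistant between centroids 1 and 2
  expect_equal(assign_clusters(rbind(c(2, 0)), model), 1L)
})

test_that("assignment is invariant under a rigid rotation of scores and centroids", {
  set.seed(8)
  s <- matrix(stats::rnorm(80), 40, 2)
  cen <- matrix(stats::rnorm(6), 3, 2)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  lab1 <- assign_clusters(s, list(centroids = cen))
  lab2 <- assign_clusters(s %*% R, list(centroids = cen %*% R))
  expect_identical(lab1, lab2)
})
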