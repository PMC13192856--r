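# NIPALS PLS engine: fit identities, orthogonalization, VIP, validation.

test_that("full-component PLS on full-rank data equals least squares", {
  fx <- make_regression(1, n = 40, p = 5)
  m <- fit_pls(fx$X, fx$y, n_components = 5)
  ols <- stats::fitted(stats::lm(fx$y ~ scale(fx$X)))
  expect_equal(as.numeric(predict(m, fx$X)), as.numeric(ols), tolerance = 1e-8)
})

test_that("single-feature PLS reduces to univariate regression on scaled data", {
  set.seed(3)
  x <- matrix(stats::rnorm(30), ncol = 1, dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + stats::rnorm(30, 0, 0.2)
  m <- fit_pls(x, y, n_components = 1)
  expect_equal(abs(m$W[1, 1]), 1, tolerance = 1e-12)
  slope <- stats::coef(stats::lm(y ~ scale(x)))[2]
  expect_equal(as.numeric(m$B), unname(slope), tolerance = 1e-8)
})

test_that("permuting sample order permutes scores identically", {
  fx <- make_regression(2, n = 30, p = 8)
  m <- fit_pls(fx$X, fx$y, n_components = 3)
  perm <- sample(seq_len(30))
  mp <- fit_pls(fx$X[perm, ], fx$y[perm], n_components = 3)
  expect_equal(mp$T, m$T[perm, ], tolerance = 1e-8)
})

test_that("score columns are mutually orthogonal", {
  fx <- make_regression(4, n = 35, p = 12)
  m <- fit_pls(fx$X, fx$y, n_components = 4)
  g <- crossprod(m$T)
  expect_true(max(abs(g[upper.tri(g)])) < 1e-8 * max(diag(g)))
})

test_that("orthogonalization preserves predictions and isolates outcome variation", {
  for (s in 1:10) {
    fx <- make_regression(s, n = 40, p = 25)
    m <- fit_pls(fx$X, fx$y, n_components = 3)
    o <- orthogonalize(m)
    expect_equal(predict(o, fx$X), predict(m, fx$X), tolerance = 1e-8)
    expect_true(all(abs(stats::cor(o$T_ortho, fx$y)) < 1e-8))
    # LV1 of the orthogonalized model is at least as outcome-aligned as any
    # plain component
    expect_gte(abs(stats::cor(o$T[, 1], fx$y)) + 1e-12,
               max(abs(stats::cor(m$T, fx$y))))
  }
})

test_that("single-component orthogonalization is a no-op with a notice", {
  fx <- make_regression(11, n = 20, p = 5)
  m <- fit_pls(fx$X, fx$y, n_components = 1)
  expect_message(o <- orthogonalize(m), "no-op")
  expect_identical(o$T, m$T)
})

test_that("VIP normalization and the two-feature analytic case hold", {
  # weights proportional to (1, 0): feature 2 orthogonal to the outcome
  set.seed(5)
  y <- stats::rnorm(50)
  x2 <- stats::residuals(stats::lm(stats::rnorm(50) ~ y))
  X <- cbind(f1 = y, f2 = x2)
  m <- fit_pls(X, y, n_components = 1)
  expect_equal(unname(vip_scores(m)), c(sqrt(2), 0), tolerance = 1e-8)
  # equal-magnitude weights give unit VIP everywhere
  X2 <- cbind(a = y + stats::rnorm(50, 0, 1e-8), b = y)
  m2 <- fit_pls(X2, y, n_components = 1)
  expect_equal(unname(vip_scores(m2)), c(1, 1), tolerance = 1e-3)
  for (s in 1:5) {
    fx <- make_regression(s + 100, n = 30, p = 10)
    mm <- fit_pls(fx$X, fx$y, n_components = 3)
    expect_equal(mean(vip_scores(mm)^2), 1, tolerance = 1e-8)
  }
})

test_that("VIP errors when the model explains no outcome variance", {
  m <- list(W = matrix(1, 2, 1), Q = matrix(0, 1, 1), tt = 1,
            P = matrix(1, 2, 1), feature_names = c("a", "b"))
  class(m) <- "pls_model"
  expect_error(vip_scores(m), "no outcome variance")
})

test_that("PLSDA separates well-separated classes and rejects singletons", {
  fx <- make_two_class(6, n = 40, p = 10, delta = 6, n_info = 10)
  m <- fit_plsda(fx$X, fx$labels, n_components = 2)
  expect_equal(mean(predict(m, fx$X, type = "class") ==
                      as.character(fx$labels)), 1)
  expect_error(fit_plsda(fx$X[1:3, ], factor(c("A", "A", "B"))), "B")
})

test_that("cross-validation is deterministic given the seed", {
  fx <- make_two_class(7, n = 20, p = 8, delta = 1)
  a <- cross_validate(fx$X, fx$labels, rounds = 5, seed = 9)
  b <- cross_validate(fx$X, fx$labels, rounds = 5, seed = 9)
  expect_identical(a$per_round, b$per_round)
})

test_that("Q2 is high for a linear signal, non-positive for pure noise, never above 1", {
  fx <- make_regression(8, n = 60, p = 10, noise = 0.05)
  q_hi <- q2_score(fx$X, fx$y, n_components = 3, seed = 2)
  expect_gt(q_hi, 0.95)
  expect_lte(q_hi, 1)
  set.seed(13)
  qs <- sapply(1:10, function(s) {
    X <- matrix(stats::rnorm(40 * 10), 40, 10)
    q2_score(X, stats::rnorm(40), seed = s)
  })
  expect_lt(mean(qs), 0.05)
  expect_error(q2_score(fx$X, rep(1, 60)), "constant")
})

test_that("rank-limited requests are reduced with a warning", {
  set.seed(21)
  X <- matrix(stats::rnorm(20), 10, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  y <- stats::rnorm(10)
  expect_warning(m <- fit_pls(X, y, n_components = 3), "rank")
  expect_lte(m$n_components, 3)
})
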