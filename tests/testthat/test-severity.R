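test_that("NCA upweights informative features in a planted-signal design", {
  set.seed(12)
  n <- 150
  X <- matrix(rnorm(n * 10), n, 10)
  y <- X[, 3] + X[, 7] + rnorm(n, 0, 0.3)
  w <- nca_regression_weights(X, y, iters = 200, seed = 1)
  expect_true(all(diff(w$objective_trace) <= 1e-9))
  expect_true(all(sort(w$w, decreasing = TRUE)[1:2] ==
                  sort(w$w[c(3, 7)], decreasing = TRUE)))
  # constant target: weights stay near uniform under the ridge pull
  w0 <- nca_regression_weights(X, rep(2, n), iters = 50, seed = 1)
  expect_lt(max(abs(w0$w - w0$w[1])), 0.2)
})

test_that("feature selection takes the k largest weights with stable ties", {
  expect_equal(select_features(c(3, 1, 2, 5), 2), c(1, 4))
  expect_equal(select_features(c(1, 1, 1, 1), 2), c(1, 2))
  expect_equal(select_features(c(2, 9, 4), 3), 1:3)
})

test_that("OLS recovers exact and noisy linear structure", {
  set.seed(7)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + 1.5 * X[, 1] - 0.5 * X[, 3]
  m <- fit_linear(X, y)
  pred <- vapply(seq_len(200), function(i)
    predict_severity(m, X[i, ])$raw, numeric(1))
  expect_lt(max(abs(pred - y)), 1e-8)

  yn <- 1 + 2 * X[, 1] + rnorm(200, 0, 0.1)
  mn <- fit_linear(X, yn)
  # coefficient on the standardized scale: beta * sd(x)
  expect_equal(unname(mn$coefficients["a"]) / mn$feature_sd["a"] * 1, 2 / 1,
               tolerance = 0.1, ignore_attr = TRUE)
  # permutation invariance
  o <- sample(200)
  mp <- fit_linear(X[o, ], yn[o])
  expect_equal(mp$coefficients, mn$coefficients, tolerance = 1e-10)
  # collinearity guard
  Xc <- cbind(X, d = X[, 1])
  expect_error(fit_linear(Xc, yn), "collinear")
})

test_that("severity predictions are affine, clamped and mean-centred", {
  set.seed(8)
  X <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("u", "v")))
  y <- 3 + X[, 1] + rnorm(100, 0, 0.2)
  m <- fit_linear(X, y)
  at_mean <- predict_severity(m, colMeans(X))
  expect_equal(at_mean$raw, mean(y), tolerance = 1e-10)
  x1 <- X[1, ]; x2 <- X[2, ]
  mix <- 0.3 * x1 + 0.7 * x2
  expect_equal(predict_severity(m, mix)$raw,
               0.3 * predict_severity(m, x1)$raw +
               0.7 * predict_severity(m, x2)$raw, tolerance = 1e-10)
  m$intercept <- 9
  expect_equal(predict_severity(m, x1)$clamped <= 5, TRUE)
  expect_error(predict_severity(m, c(u = 1)), "missing feature")
})

test_that("k-fold CV is seed-stable and honest about noise", {
  set.seed(10)
  X <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  y_exact <- 1 + X %*% c(1, -1, 0.5)
  cv0 <- kfold_cv(X, as.numeric(y_exact), k = 5, seed = 2)
  expect_lt(cv0$mse_mean, 1e-10)
  expect_identical(cv0$fold_assignments,
                   kfold_cv(X, as.numeric(y_exact), k = 5, seed = 2)$fold_assignments)
  expect_equal(unname(table(cv0$fold_assignments)), rep(60L, 5), ignore_attr = TRUE)

  y_noise <- rnorm(300)
  cvn <- kfold_cv(X, y_noise, k = 5, seed = 3)
  expect_lt(abs(cvn$mse_mean - var(y_noise)) / var(y_noise), 0.2)
})

test_that("group t-tests separate separated groups and star correctly", {
  set.seed(11)
  f <- data.frame(F1 = c(rnorm(50, 0, 1), rnorm(50, 5, 1)))
  rsd <- rep(c(1L, 3L), each = 50)
  tt <- group_ttests(f, rsd)
  expect_lt(tt$p_value[1], 0.001)
  expect_equal(tt$stars[1], "***")
  same <- data.frame(F1 = rep(c(1, 2), 10))
  tt2 <- group_ttests(same, rep(c(1L, 2L), each = 10))
  expect_true(all(!tt2$skipped))
  expect_equal(plusquant:::p_stars(0.03), "*")
  expect_equal(plusquant:::p_stars(0.0005), "***")
  expect_equal(plusquant:::p_stars(0.2), "")
  # underpowered level skipped with a flag
  tt3 <- group_ttests(data.frame(F1 = c(1, 2, 3)), c(1L, 1L, 2L))
  expect_true(all(tt3$skipped))
})

test_that("severity models round-trip through JSON", {
  set.seed(13)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 + X[, 1] + rnorm(60, 0, 0.1)
  m <- fit_linear(X, y)
  d <- withr::local_tempdir()
  save_severity_model(m, file.path(d, "m.json"))
  m2 <- load_severity_model(file.path(d, "m.json"))
  expect_equal(predict_severity(m2, X[5, ])$raw,
               predict_severity(m, X[5, ])$raw, tolerance = 1e-12)
})
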