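test_that("a single informative column gives a perfect univariate fit", {
  set.seed(51)
  y <- stats::runif(20, 0, 2)
  X <- cbind(0.5 * y, matrix(0, 20, 4))
  m <- fit_plsr(X, y, 1)
  expect_equal(unname(predict(m, X)), y, tolerance = 1e-10)
  expect_lt(max(abs(m$b[-1])), 1e-10)
})

test_that("PLS at full rank equals ordinary least squares", {
  set.seed(52)
  X <- matrix(stats::rnorm(20 * 8), 20, 8)
  y <- stats::rnorm(20)
  m <- fit_plsr(X, y, 8)
  Xc <- sweep(X, 2, colMeans(X))
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  pred_ols <- mean(y) + drop(Xc %*% b_ols)
  expect_lt(max(abs(predict(m, X) - pred_ols)), 1e-6)
})

test_that("NIPALS scores are orthogonal and weights unit-norm", {
  set.seed(53)
  X <- matrix(stats::rnorm(15 * 10), 15, 10)
  y <- stats::rnorm(15)
  m <- fit_plsr(X, y, 4)
  TtT <- crossprod(m$TT)
  expect_lt(max(abs(TtT[upper.tri(TtT)])), 1e-8)
  expect_equal(unname(colSums(m$W^2)), rep(1, 4), tolerance = 1e-10)
  expect_error(fit_plsr(X, y, 15), "rank")
  expect_error(fit_plsr(X, rep(1, 15), 2), "variance")
})

test_that("prediction is the centred linear form", {
  set.seed(54)
  X <- matrix(stats::rnorm(12 * 6), 12, 6)
  y <- stats::rnorm(12)
  m <- fit_plsr(X, y, 3)
  # the mean spectrum predicts the mean response
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean, tolerance = 1e-10)
  expect_equal(unname(predict(m, X)),
               unname(m$y_mean + drop(sweep(X, 2, m$x_mean) %*% m$b)))
  expect_error(predict(m, X[, 1:3]), "axis")
})

test_that("cross-validation recovers a noise-free linear system", {
  set.seed(55)
  L <- matrix(stats::rnorm(2 * 25), 2, 25)
  S <- matrix(stats::runif(18 * 2), 18, 2)
  X <- S %*% L
  y <- drop(S %*% c(1, -2))
  cv <- cross_validate(X, y, max_lv = 4)
  expect_lt(cv$table$rmsecv[2], 1e-8)
  expect_gt(cv$table$q2[2], 1 - 1e-10)
  expect_lte(cv$selected_lv, 4)
})

test_that("permuted responses have no predictive power", {
  set.seed(56)
  X <- matrix(stats::rnorm(24 * 30), 24, 30)
  y <- stats::runif(24, 0, 2)
  q2s <- replicate(20, {
    cv <- cross_validate(X, sample(y), max_lv = 2)
    cv$table$q2[2]
  })
  expect_lte(stats::median(q2s), 0)
})

test_that("cross-validated fit does not beat the training fit", {
  set.seed(57)
  diffs <- replicate(20, {
    X <- matrix(stats::rnorm(15 * 12), 15, 12)
    y <- drop(X[, 1] - X[, 2]) + stats::rnorm(15, sd = 0.5)
    m <- calibration_metrics(X, y, max_lv = 3)
    m$metrics$r2 - m$metrics$q2
  })
  expect_gte(stats::median(diffs), 0)
})

test_that("calibration metrics hit their degenerate limits", {
  set.seed(58)
  # noiseless: perfect training fit and cross-validation
  y <- seq(0, 2, length.out = 12)
  X <- cbind(y, y^2)
  m <- calibration_metrics(X, y, X_test = X * 1, y_test = y,
                           train_ids = paste0("a", 1:12),
                           test_ids = paste0("b", 1:12), max_lv = 2)
  expect_equal(m$metrics$r2, 1, tolerance = 1e-8)
  expect_equal(m$metrics$q2, 1, tolerance = 1e-6)
  expect_lt(m$metrics$rmsecv, 1e-6)
  expect_lt(m$metrics$rmsep, 1e-8)
  expect_error(
    calibration_metrics(X, y, train_ids = "s1", test_ids = "s1"),
    "overlap")
  # an orthogonal predictor offers no latent direction at all
  yc <- c(rep(1, 6), rep(3, 6))
  expect_error(fit_plsr(matrix(rep(c(1, 2), 6), 12, 1), yc, 1),
               "uncorrelated")
})

test_that("effectively-zero flags require a cross-validated error", {
  set.seed(59)
  X <- matrix(stats::rnorm(12 * 5), 12, 5)
  y <- stats::runif(12, 0, 2)
  m <- fit_plsr(X, y, 2)
  expect_error(predict(m, X, flag = TRUE), "RMSECV")
  m$metrics$rmsecv <- 0.5
  out <- predict(m, X, flag = TRUE)
  expect_true(all(out$effectively_zero == (abs(out$predicted_mM) < 0.5)))
})

test_that("NIPALS agrees with an independent PLS implementation", {
  set.seed(60)
  X <- matrix(stats::rnorm(20 * 15), 20, 15,
              dimnames = list(NULL, paste0("v", 1:15)))
  y <- drop(X %*% stats::rnorm(15)) + stats::rnorm(20, sd = 0.3)
  m <- fit_plsr(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  pref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(predict(m, X)), unname(pref), tolerance = 1e-6)
})
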