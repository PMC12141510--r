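test_that("ALS baseline reproduces flat and linear backgrounds exactly", {
  expect_equal(als_baseline(rep(3.7, 200)), rep(3.7, 200), tolerance = 1e-8)
  x <- seq(0, 1, length.out = 300)
  line <- 2 + 5 * x
  est <- als_baseline(line, lam = 1e8)
  expect_lt(max(abs(est - line)), 1e-6 * diff(range(line)))
  expect_error(als_baseline(c(1, NA, 3, 4)), "non-finite")
  expect_error(als_baseline(c(1, 2)), "3 points")
  expect_error(als_baseline(1:10, p = 1.5), "p must")
})

test_that("ALS recovers a known baseline under peaks and preserves areas", {
  axis <- seq(400, 2300, 1)
  lor <- function(c, w, a) a / (1 + ((axis - c) / (w / 2))^2)
  peaks <- lor(700, 14, 1) + lor(1300, 12, 0.8) + lor(1900, 16, 0.6)
  u <- (axis - 400) / 1900
  true_bl <- 0.5 + 0.8 * u + 0.6 * u^2 + 0.2 * u^3
  est <- als_baseline(peaks + true_bl)
  core <- abs(axis - 700) < 3 * 14 | abs(axis - 1300) < 3 * 12 |
    abs(axis - 1900) < 3 * 16
  expect_lt(max(abs(est - true_bl)[!core]), 0.05 * max(peaks))
  # peak areas survive baseline subtraction to within 5%
  corrected <- subtract_baseline(peaks + true_bl, est)
  for (pw in list(c(700, 14), c(1300, 12), c(1900, 16))) {
    reg <- abs(axis - pw[1]) < 2.5 * pw[2]
    expect_lt(abs(sum(corrected[reg]) - sum(peaks[reg])) / sum(peaks[reg]),
              0.05)
  }
  # asymmetry: baseline sits at or below every peak apex
  apex <- vapply(c(700, 1300, 1900), function(c0) which.min(abs(axis - c0)),
                 integer(1))
  expect_true(all(est[apex] <= (peaks + true_bl)[apex]))
})

test_that("baseline subtraction is pointwise and validates axes", {
  y <- stats::rnorm(50)
  expect_equal(subtract_baseline(y, y), rep(0, 50))
  expect_equal(subtract_baseline(y, rep(0, 50)), y)
  s1 <- spectrum(1:50, y)
  s2 <- spectrum(2:51, y)
  expect_error(subtract_baseline(s1, s2), "axes differ")
  expect_error(subtract_baseline(y, y[1:10]), "length mismatch")
})

test_that("Savitzky-Golay matches the per-window polyfit oracle", {
  set.seed(101)
  y <- stats::rnorm(101)
  expect_lt(max(abs(savitzky_golay(y, 11, 2) - sg_oracle(y, 11, 2))), 1e-10)
  expect_lt(max(abs(savitzky_golay(y, 7, 3) - sg_oracle(y, 7, 3))), 1e-10)
})

test_that("Savitzky-Golay reproduces polynomials and is linear", {
  x <- seq(-2, 2, length.out = 60)
  quad <- 1 + 2 * x + 3 * x^2
  expect_equal(savitzky_golay(quad, 11, 2), quad, tolerance = 1e-12)
  expect_equal(savitzky_golay(rep(5, 40), 11, 2), rep(5, 40),
               tolerance = 1e-12)
  set.seed(7)
  y1 <- stats::rnorm(80); y2 <- stats::rnorm(80)
  expect_lt(max(abs(savitzky_golay(2 * y1 - 3 * y2, 11, 2) -
                      (2 * savitzky_golay(y1, 11, 2) -
                         3 * savitzky_golay(y2, 11, 2)))), 1e-10)
  expect_error(savitzky_golay(y1, 10, 2), "odd")
  expect_error(savitzky_golay(y1, 3, 4), "exceed")
  expect_error(savitzky_golay(y1[1:5], 11, 2), "shorter")
})

test_that("vector normalization scales to unit norm", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  set.seed(9)
  y <- stats::rnorm(30)
  expect_equal(vector_normalize(y), vector_normalize(10 * y))
  v <- vector_normalize(y)
  expect_equal(vector_normalize(v), v)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  expect_error(vector_normalize(rep(0, 5)), "all-zero")
})

test_that("preprocessing paths compose the stages in the specified order", {
  cfg <- sim_config(seed = 21, carotene_conc = 0.5)
  set <- simulate_calibration_set(0, 0.4, 0.2, 2, cfg)
  pls <- preprocess_set(set, "plsr_path")
  norms <- apply(pls$intensities, 2, function(c) sqrt(sum(c^2)))
  expect_equal(unname(norms), rep(1, n_spectra(set)), tolerance = 1e-12)
  expect_identical(pls$metadata, set$metadata)
  # pca_path == normalize(smooth(subtract(y, als(y)))) per spectrum
  pca <- preprocess_set(set, "pca_path")
  manual <- vector_normalize(savitzky_golay(subtract_baseline(
    set$intensities[, 3], als_baseline(set$intensities[, 3]))))
  expect_equal(unname(pca$intensities[, 3]), manual, tolerance = 1e-12)
  # empty set passes through without error
  empty <- spectrum_set(set$axis,
                        matrix(numeric(0), length(set$axis), 0),
                        data.frame(spectrum_id = character(0)))
  expect_equal(n_spectra(preprocess_set(empty, "plsr_path")), 0)
})
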