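test_that("band integration matches analytic areas", {
  x <- 400:1800
  expect_equal(band_area(spectrum(x, rep(0, length(x)))), 0)
  # unit-height rectangle exactly on [715, 750]
  rect <- spectrum(x, as.numeric(x >= 715 & x <= 750))
  expect_equal(band_area(rect), 35)
  # triangle, height h, base 35, centered at 732.5, on a 0.1 1/cm grid
  xf <- seq(400, 1800, by = 0.1)
  h <- 3.7
  tri <- pmax(0, h * (1 - abs(xf - 732.5) / 17.5))
  expect_equal(band_area(spectrum(xf, tri)), h * 35 / 2, tolerance = 1e-3)
  expect_error(band_area(spectrum(800:1800, rep(1, 1001))), "band window")
})

test_that("sample responses average replicates symmetrically", {
  x <- 700:760
  mk <- function(a) spectrum(x, rep(a / 35, length(x)))
  reps <- lapply(c(1, 2, 3), mk)
  expect_equal(as.numeric(sample_response(list(mk(5)))), band_area(mk(5)))
  m <- sample_response(reps)
  expect_equal(as.numeric(m), mean(vapply(reps, band_area, 0)))
  expect_equal(attr(m, "n_replicates"), 3L)
  expect_equal(as.numeric(sample_response(rev(reps))), as.numeric(m))
  expect_error(sample_response(list()), "at least one")
})

test_that("an exact line is fitted perfectly and flagged suitable", {
  fit <- fit_inverse_calibration(c(1, 2, 3), c(10, 20, 30))
  expect_equal(unname(coef(fit)), c(0, 10), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$suitable)
  expect_equal(fit$cal_range, c(10, 30))
  expect_equal(predict(fit, 2.5), 25, ignore_attr = TRUE)
  expect_equal(predict(fit, 0), unname(coef(fit)[1]), ignore_attr = TRUE)
  expect_error(fit_inverse_calibration(c(2, 2, 2), c(1, 2, 3)), "degenerate")
})

test_that("OLS invariants hold: zero residual sum and scale equivariance", {
  set.seed(21)
  for (i in 1:10) {
    a <- runif(8, 1, 50)
    cc <- 2 + 0.7 * a + rnorm(8)
    fit <- fit_inverse_calibration(a, cc)
    expect_lt(abs(sum(residuals(fit))), 1e-10)
    expect_equal(predict(fit, a, override_suitability = TRUE),
                 fit$fitted, ignore_attr = TRUE, tolerance = 1e-10)
    k <- 37.5
    fit_k <- fit_inverse_calibration(a * k, cc)
    expect_equal(coef(fit_k)[["b1"]], coef(fit)[["b1"]] / k, tolerance = 1e-9)
    expect_equal(predict(fit_k, a * k, override_suitability = TRUE),
                 predict(fit, a, override_suitability = TRUE),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("the r^2 component of the suitability gate flips exactly at 0.6", {
  below <- make_r2_pairs(0.59)
  above <- make_r2_pairs(0.61)
  f_below <- fit_inverse_calibration(below)
  f_above <- fit_inverse_calibration(above)
  expect_gt(f_below$r_squared, 0.58); expect_lt(f_below$r_squared, 0.60)
  expect_gt(f_above$r_squared, 0.60); expect_lt(f_above$r_squared, 0.62)
  expect_true("r2_below_threshold" %in% f_below$reasons)
  expect_false("r2_below_threshold" %in% f_above$reasons)
  expect_false(f_below$suitable)
})

test_that("pure-noise calibrations are rejected with high probability", {
  set.seed(31)
  rejected <- vapply(1:200, function(i) {
    !fit_inverse_calibration(rnorm(10), rnorm(10))$suitable
  }, NA)
  expect_gt(mean(rejected), 0.95)
})

test_that("unsuitable models refuse to predict unless overridden", {
  set.seed(8)
  fit <- fit_inverse_calibration(rnorm(10), rnorm(10))
  expect_false(fit$suitable)
  expect_error(predict(fit, 1), "not suitable")
  expect_silent(predict(fit, 1, override_suitability = TRUE))
})

test_that("predictions flag but never clip out-of-range values", {
  fit <- fit_inverse_calibration(c(1, 2, 3), c(10, 20, 30))
  p <- predict(fit, c(0.5, 2, 5, -1))
  expect_equal(as.numeric(p), c(5, 20, 50, -10))
  expect_equal(attr(p, "out_of_range"), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("a single experiment predicts all test levels exactly when noise-free", {
  g <- generate_collection(noise_free_config(labs_per_method = 1L))
  pp <- run_preprocess(g$datasets[[1]])
  ex <- run_experiment(pp)
  expect_equal(nrow(ex$records), 5)  # one record per test level
  expect_true(ex$model$suitable)
  expect_lt(max(abs(ex$records$residual) / ex$records$reference), 1e-9)
  expect_equal(ex$records$residual,
               ex$records$predicted - ex$records$reference)
})

test_that("a dataset failing suitability yields no records and a reason", {
  # drown the analyte band in noise so the calibration has no slope signal
  g <- generate_collection(tiny_config(labs_per_method = 1L,
                                       response_amplitude = 0.001,
                                       noise_sd_additive = 30))
  pp <- run_preprocess(g$datasets[[1]])
  ex <- run_experiment(pp)
  expect_false(ex$model$suitable)
  expect_equal(nrow(ex$records), 0)
  expect_match(ex$reason, "r2_below_threshold|f_test_not_significant")
})

test_that("replicate handling supports per-replicate fitting", {
  g <- generate_collection(noise_free_config(labs_per_method = 1L))
  pp <- run_preprocess(g$datasets[[1]])
  ex_mean <- run_experiment(pp, replicate_handling = "mean")
  ex_ind <- run_experiment(pp, replicate_handling = "individual")
  expect_equal(ex_ind$model$n_points, 3 * ex_mean$model$n_points)
  # identical replicates: both routes give one and the same line
  expect_equal(coef(ex_ind$model), coef(ex_mean$model), tolerance = 1e-9)
})
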