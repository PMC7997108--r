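test_that("Savitzky-Golay smoothing reproduces low-order polynomials and cuts noise", {
  x <- 400:1400
  const <- spectrum(x, rep(7, length(x)))
  expect_equal(smooth_spectrum(const)$intensity, const$intensity)
  line <- spectrum(x, 0.5 * x - 100)
  expect_equal(smooth_spectrum(line, 9, 2)$intensity, line$intensity,
               tolerance = 1e-10)
  set.seed(11)
  noisy <- spectrum(seq_len(1000) + 399, rnorm(1000, 0, 3))
  expect_lt(sd(smooth_spectrum(noisy)$intensity), sd(noisy$intensity))
  expect_error(smooth_spectrum(const, window = 8), "odd")
  expect_error(smooth_spectrum(const, window = 5, polyorder = 5), "polyorder")
  expect_error(smooth_spectrum(spectrum(1:5, 1:5), window = 7), "exceeds")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  x <- 400:800
  s <- spectrum(x, 2 * x)
  expect_equal(resample_spectrum(s, x)$intensity, s$intensity)
  r <- resample_spectrum(s, c(400, 800, 2))
  expect_equal(r$intensity, 2 * r$wavenumber)  # exact for a line
  expect_error(resample_spectrum(s, c(300, 800, 2)), "beyond source range")
})

test_that("cropping keeps the closed interval", {
  s <- spectrum(400:1800, rnorm(1401))
  cr <- crop_spectrum(s, 600, 1000)
  expect_equal(range(cr$wavenumber), c(600, 1000))
  expect_length(cr$wavenumber, 401)
  expect_equal(crop_spectrum(s, 400, 1800), s)
  expect_error(crop_spectrum(s, 2000, 2100), "fewer than 2")
})

test_that("baseline methods recover their model classes", {
  x <- 400:1400
  zero <- spectrum(x, rep(0, length(x)))
  bc <- baseline_correct(zero, "als")
  expect_equal(max(abs(bc$corrected$intensity)), 0)
  expect_equal(max(abs(bc$baseline$intensity)), 0)

  # a pure cubic is reproduced by the iterative polynomial fit
  poly3 <- spectrum(x, 1e-6 * (x - 900)^3 + 0.01 * x + 5)
  bc3 <- baseline_correct(poly3, "modpoly", degree = 3)
  expect_lt(max(abs(bc3$corrected$intensity)), 1e-6 * max(abs(poly3$intensity)))

  # polynomial + one narrow band: band height preserved within 5%
  h <- 80
  band <- h * exp(-(x - 900)^2 / (2 * 6^2))
  sb <- spectrum(x, 20 + 0.02 * x + band)
  for (m in c("als", "aspoly")) {
    got <- baseline_correct(sb, m)$corrected
    expect_lt(abs(max(got$intensity) - h) / h, 0.05, label = m)
  }
})

test_that("EMSC recovers gain and additive background exactly", {
  x <- 400:1800
  ref <- spectrum(x, 100 * exp(-(x - 900)^2 / (2 * 40^2)) +
                    60 * exp(-(x - 1300)^2 / (2 * 25^2)) + 10)
  # identity input
  e0 <- emsc(ref, ref, poly_degree = 2)
  expect_equal(e0$b, 1, tolerance = 1e-12)
  expect_equal(max(abs(e0$poly_coef)), 0, tolerance = 1e-9)
  expect_equal(e0$corrected$intensity, ref$intensity, tolerance = 1e-12)
  # gain 2 plus offset 0.5
  s <- spectrum(x, 2 * ref$intensity + 0.5)
  e1 <- emsc(s, ref, poly_degree = 2)
  expect_equal(e1$b, 2, tolerance = 1e-12)
  expect_equal(unname(e1$poly_coef[1]), 0.5, tolerance = 1e-9)
  expect_equal(unname(e1$poly_coef[2]), 0, tolerance = 1e-12)
  expect_equal(e1$corrected$intensity, ref$intensity, tolerance = 1e-9)
  # constant spectrum is orthogonal to the reference model
  expect_error(emsc(spectrum(x, rep(3, length(x))), ref), "orthogonal")
  # applying EMSC twice changes nothing (second gain is 1)
  e2 <- emsc(e1$corrected, ref, poly_degree = 2)
  expect_equal(e2$b, 1, tolerance = 1e-9)
  expect_equal(e2$corrected$intensity, e1$corrected$intensity,
               tolerance = 1e-9)
})

test_that("EMSC removes a pure gain for any g != 0", {
  x <- 400:1800
  ref <- spectrum(x, 50 * exp(-(x - 1000)^2 / (2 * 60^2)) + 5)
  for (g in c(-2, 0.01, 0.5, 7)) {
    e <- emsc(spectrum(x, g * ref$intensity), ref)
    expect_equal(e$b, g, tolerance = 1e-9)
    expect_equal(e$corrected$intensity, ref$intensity,
                 tolerance = 1e-9 * max(abs(ref$intensity)))
  }
})

test_that("preprocessing makes equal concentrations superimposable across labs", {
  cfg <- noise_free_config(lab_gain_sd = 0.3)  # labs differ only by gain
  g <- generate_collection(cfg)
  pp <- lapply(g$datasets, run_preprocess)
  s1 <- pp[[1]]$calibration[[1]]
  s2 <- pp[[2]]$calibration[[1]]
  expect_equal(s1$meta$concentration, s2$meta$concentration)
  scale <- max(abs(s1$intensity))
  expect_lt(max(abs(s1$intensity - s2$intensity)) / scale, 1e-6)
  # metadata untouched, axis is the 1 1/cm intersection grid
  expect_identical(s1$meta, g$datasets[[1]]$calibration[[1]]$meta)
  expect_equal(diff(s1$wavenumber)[1], 1)
})

test_that("the preprocess stage order and provenance are logged", {
  g <- generate_collection(tiny_config(labs_per_method = 1L))
  pp <- run_preprocess(g$datasets[[1]])
  line <- pp$provenance[length(pp$provenance)]
  expect_match(line, "sgolay.*resample.*crop.*aspoly.*emsc")
  # identical rerun gives identical output (pipeline is deterministic)
  pp2 <- run_preprocess(g$datasets[[1]])
  expect_equal(lapply(pp$calibration, `[[`, "intensity"),
               lapply(pp2$calibration, `[[`, "intensity"))
})

test_that("preprocess configuration validates its parameters", {
  expect_error(preprocess_config(smooth_window = 8), "odd")
  expect_error(preprocess_config(smooth_polyorder = 9), "odd smooth_window")
  expect_error(preprocess_config(emsc_poly_degree = -1), "emsc_poly_degree")
  expect_error(preprocess_config(baseline_method = "magic"), "unknown baseline")
  cfg <- preprocess_config(baseline_params = list(degree = 2L))
  expect_equal(cfg$baseline_params$degree, 2L)
  expect_equal(cfg$baseline_params$p, 0.01)
})
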