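test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- tiny_config()
  set.seed(123)
  before <- .Random.seed
  g1 <- generate_collection(cfg)
  expect_identical(.Random.seed, before)
  g2 <- generate_collection(cfg)
  expect_identical(
    lapply(g1$datasets, function(d) lapply(c(d$calibration, d$test), `[[`, "intensity")),
    lapply(g2$datasets, function(d) lapply(c(d$calibration, d$test), `[[`, "intensity")))
  expect_identical(g1$truth$spectra, g2$truth$spectra)
  # a different seed changes the data
  g3 <- generate_collection(tiny_config(seed = 43L))
  expect_false(identical(g1$datasets[[1]]$calibration[[1]]$intensity,
                         g3$datasets[[1]]$calibration[[1]]$intensity))
})

test_that("collection size follows methods x labs x levels x replicates", {
  # six colloidal methods, 8 labs, 9 cal + 5 test levels, 3 replicates
  cfg <- synth_config(
    methods = c("cAg@532", "cAg@785", "cAu@532", "cAu@785", "cAg@633", "cAu@633"),
    labs_per_method = 8L, seed = 5L)
  g <- generate_collection(cfg)
  expect_length(g$datasets, 48)
  n_spec <- sum(vapply(g$datasets,
                       function(d) length(d$calibration) + length(d$test), 0L))
  expect_equal(n_spec, 8 * 6 * (9 + 5) * 3)
  expect_equal(nrow(g$truth$spectra), n_spec)
  # solid substrates carry 9 replicates per sample
  gs <- generate_collection(tiny_config(methods = "sAg@785", labs_per_method = 1L))
  expect_equal(length(gs$datasets[[1]]$calibration), 5 * 9)
})

test_that("noise-free band areas equal amplitude x concentration x window fraction", {
  cfg <- noise_free_config(labs_per_method = 1L,
                           baseline_poly_coeffs = 0,
                           matrix_bands = data.frame(center = numeric(),
                                                     fwhm = numeric(),
                                                     area = numeric()))
  g <- generate_collection(cfg)
  frac <- oracle_window_fraction(cfg$band_center, cfg$band_fwhm, 715, 750)
  for (s in g$datasets[[1]]$calibration) {
    expected <- cfg$response_amplitude * s$meta$concentration * frac
    expect_equal(band_area(s), expected, tolerance = 1e-10)
  }
  # truth record agrees with the same oracle
  tr <- g$truth$spectra
  expect_equal(tr$true_band_area,
               cfg$response_amplitude * tr$concentration * frac,
               tolerance = 1e-10)
})

test_that("generated band area is monotone in concentration for any K > 0", {
  conc <- c(0, 0.5, 1, 5, 20, 100, 500)
  for (K in c(2, 50, 1e4, Inf)) {
    cfg <- noise_free_config(labs_per_method = 1L, saturation_K = K,
                             cal_concentrations = conc,
                             test_concentrations = numeric())
    g <- generate_collection(cfg)
    cal <- g$datasets[[1]]$calibration
    cc <- vapply(cal, function(s) s$meta$concentration, 0)
    a <- vapply(cal, band_area, 0)[order(cc)]
    expect_true(all(diff(a) >= -1e-9), info = paste("K =", K))
  }
})

test_that("saturating response bends below the linear one", {
  cfg_lin <- noise_free_config(labs_per_method = 1L, saturation_K = Inf)
  cfg_sat <- noise_free_config(labs_per_method = 1L, saturation_K = 50)
  a_lin <- vapply(generate_collection(cfg_lin)$datasets[[1]]$calibration,
                  band_area, 0)
  a_sat <- vapply(generate_collection(cfg_sat)$datasets[[1]]$calibration,
                  band_area, 0)
  expect_true(all(a_sat <= a_lin + 1e-9))
  conc <- vapply(generate_collection(cfg_lin)$datasets[[1]]$calibration,
                 function(s) s$meta$concentration, 0)
  ratio <- (a_lin - a_sat)[order(conc)]
  expect_true(all(diff(ratio) >= -1e-9))  # shortfall grows with concentration
})

test_that("lab gains and contamination are recorded in the truth object", {
  cfg <- tiny_config(contaminant_prob = 1, labs_per_method = 1L)
  g <- generate_collection(cfg)
  expect_true(all(g$truth$contaminated))
  expect_length(g$truth$lab_gain, 1L)
  # contaminated spectra sit well above the clean model in the 1440 band
  s <- g$datasets[[1]]$calibration[[1]]
  ref <- contaminant_reference(cfg)
  peak_region <- s$wavenumber >= 1430 & s$wavenumber <= 1450
  expect_true(mean(s$intensity[peak_region]) >
                mean(ref$intensity[peak_region]) * 0.5)
  clean <- generate_collection(tiny_config(contaminant_prob = 0,
                                           labs_per_method = 1L))
  expect_false(any(clean$truth$contaminated))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(synth_config(lab_gain_sd = -0.1))
  expect_error(synth_config(contaminant_prob = 1.5))
  expect_error(synth_config(axis = c(1800, 400, 1)))
  expect_error(synth_config(cal_concentrations = c(5, 5)), "distinct")
  expect_s3_class(ils_study_config(), "sers_synth_config")
  expect_length(ils_study_config()$methods, 6L)
})
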