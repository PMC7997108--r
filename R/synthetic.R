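#' Unit-area pseudo-Voigt band profile
#'
#' 50/50 mixture of a Gaussian and a Lorentzian sharing one full width at
#' half maximum, normalized so the profile integrates to 1 over the whole
#' axis. Multiplying by a band area therefore yields a band of that area.
#'
#' @param x wavenumbers (1/cm).
#' @param center band center (1/cm).
#' @param fwhm full width at half maximum (1/cm).
#' @return numeric profile values.
#' @export
pseudo_voigt <- function(x, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- stats::dnorm(x, mean = center, sd = sigma)
  gamma <- fwhm / 2
  l <- (gamma / pi) / ((x - center)^2 + gamma^2)
  0.5 * g + 0.5 * l
}

# Band profile used by the generator: pseudo-Voigt truncated to a finite
# support of +/- support_fwhm half-widths and renormalized to unit area on
# the generation grid. The truncation confines each simulated band strictly
# to its neighbourhood, so spectral regions away from a band carry exactly
# zero analyte signal (the Lorentzian half would otherwise contribute
# slowly decaying tails across the whole axis).
band_profile <- function(x, center, fwhm, support_fwhm = 5) {
  p <- pseudo_voigt(x, center, fwhm)
  p[abs(x - center) > support_fwhm * fwhm] <- 0
  a <- trapz(x, p)
  if (a <= 0) stop_serscal("band support does not overlap the axis")
  p / a
}

#' Configuration of the synthetic interlaboratory generator
#'
#' Defines the statistical structure of a simulated multi-laboratory SERS
#' study of a single analyte quantified through one band. Each generated
#' spectrum follows
#' `I(v) = baseline(v) + g_lab * [A(c) * (1 + delta_rep) * profile(v) + matrix(v)] + contaminant(v) + noise(v)`
#' where `A(c) = response_amplitude * c * K / (K + c)` (linear when `K` is
#' infinite), `profile` is a unit-area pseudo-Voigt band (truncated to a
#' +/- 5 FWHM support and renormalized, so a band contributes no signal far
#' from its center), `matrix(v)` is a
#' fixed set of concentration-invariant bands (buffer/substrate background,
#' which also anchors the EMSC gain estimate), `g_lab ~ N(1, lab_gain_sd)`
#' is a per-laboratory gain, `delta_rep ~ N(0, replicate_sd)` is a
#' per-replicate enhancement fluctuation affecting the analyte band only,
#' and the additive noise has pointwise SD
#' `noise_sd_additive + noise_sd_proportional * A(c)`.
#'
#' With probability `contaminant_prob` a dataset's spectra receive two
#' additive contaminant ("parafilm-like") bands, one inside and one outside
#' the analyte window, to exercise the integrity screen.
#'
#' @param methods character vector of method codes (see [method_id()]).
#' @param labs_per_method laboratories simulated per method.
#' @param cal_concentrations calibration concentrations, µM.
#' @param test_concentrations test concentrations, µM.
#' @param band_center,band_fwhm analyte band position and width, 1/cm.
#' @param response_amplitude band area per µM at low concentration.
#' @param saturation_K Langmuir-type saturation constant, µM (`Inf` for a
#'   linear response).
#' @param lab_gain_sd,replicate_sd relative SDs of the lab gain and
#'   replicate fluctuation.
#' @param noise_sd_additive,noise_sd_proportional additive noise floor
#'   (counts) and concentration-proportional component (fraction of `A(c)`).
#' @param baseline_poly_coeffs polynomial coefficients (in raw wavenumber,
#'   constant first) of the smooth fluorescence baseline.
#' @param matrix_bands data frame with columns `center`, `fwhm`, `area` of
#'   the fixed background bands.
#' @param contaminant_prob probability a dataset is contaminated.
#' @param contaminant_area area of each contaminant band.
#' @param axis `c(start, stop, step)` wavenumber grid, 1/cm.
#' @param seed integer RNG seed.
#' @return an object of class `sers_synth_config` (a validated list).
#' @export
synth_config <- function(methods = default_methods(),
                         labs_per_method = 8L,
                         cal_concentrations = 10^seq(0, 2, length.out = 9),
                         test_concentrations = 10^seq(0.375, 1.875,
                                                      length.out = 5),
                         band_center = 733, band_fwhm = 14,
                         response_amplitude = 50,
                         saturation_K = Inf,
                         lab_gain_sd = 0.15, replicate_sd = 0.2,
                         noise_sd_additive = 1,
                         noise_sd_proportional = 0.005,
                         baseline_poly_coeffs = c(150, -0.08, 1.5e-5),
                         matrix_bands = data.frame(
                           center = c(960, 1095, 1450),
                           fwhm = c(20, 25, 18),
                           area = c(2000, 2500, 1500)),
                         contaminant_prob = 0,
                         contaminant_area = 8000,
                         axis = c(400, 1800, 1),
                         seed = 1L) {
  stopifnot(lab_gain_sd >= 0, replicate_sd >= 0, noise_sd_additive >= 0,
            noise_sd_proportional >= 0,
            all(cal_concentrations >= 0), all(test_concentrations >= 0),
            contaminant_prob >= 0, contaminant_prob <= 1,
            axis[3] > 0, axis[2] > axis[1],
            saturation_K > 0)
  for (m in methods) parse_method_id(m, allowed = NULL)
  if (length(unique(cal_concentrations)) < 2L)
    stop_serscal("need at least 2 distinct calibration concentrations")
  structure(list(methods = methods,
                 labs_per_method = as.integer(labs_per_method),
                 cal_concentrations = as.numeric(cal_concentrations),
                 test_concentrations = as.numeric(test_concentrations),
                 band_center = band_center, band_fwhm = band_fwhm,
                 response_amplitude = response_amplitude,
                 saturation_K = saturation_K,
                 lab_gain_sd = lab_gain_sd, replicate_sd = replicate_sd,
                 noise_sd_additive = noise_sd_additive,
                 noise_sd_proportional = noise_sd_proportional,
                 baseline_poly_coeffs = as.numeric(baseline_poly_coeffs),
                 matrix_bands = matrix_bands,
                 contaminant_prob = contaminant_prob,
                 contaminant_area = contaminant_area,
                 axis = axis, seed = as.integer(seed)),
            class = "sers_synth_config")
}

#' Study-scale default configuration
#'
#' A documented default emulating the scale of a full collaborative SERS
#' trial: 6 methods (all of [default_methods()]), 8 laboratories per method,
#' 9 calibration levels C0-C8 log-spaced over 1-100 µM, and 5 test levels
#' X1-X5 interleaved inside the calibration range; replicate counts follow
#' the substrate scheme (3 colloidal, 9 solid).
#'
#' @param ... overrides passed on to [synth_config()].
#' @return a `sers_synth_config`.
#' @export
ils_study_config <- function(...) synth_config(...)

# Expected (noise-free, unit-gain) analyte response at concentration c.
band_amplitude <- function(cfg, conc) {
  if (is.finite(cfg$saturation_K)) {
    cfg$response_amplitude * conc * cfg$saturation_K /
      (cfg$saturation_K + conc)
  } else {
    cfg$response_amplitude * conc
  }
}

synth_baseline <- function(cfg, x) {
  b <- numeric(length(x))
  for (k in seq_along(cfg$baseline_poly_coeffs))
    b <- b + cfg$baseline_poly_coeffs[k] * x^(k - 1)
  b
}

synth_matrix <- function(cfg, x) {
  m <- numeric(length(x))
  mb <- cfg$matrix_bands
  if (!is.null(mb) && nrow(mb))
    for (i in seq_len(nrow(mb)))
      m <- m + mb$area[i] * band_profile(x, mb$center[i], mb$fwhm[i])
  m
}

#' Pure contaminant reference spectrum
#'
#' The two "parafilm-like" bands (733 and 1440 1/cm, one inside and one
#' outside the analyte window) that [generate_collection()] adds to
#' contaminated datasets, without baseline or noise. Suitable as a
#' reference for [integrity_check()].
#'
#' @param cfg a [synth_config()].
#' @return a [spectrum()].
#' @export
contaminant_reference <- function(cfg = synth_config()) {
  x <- expand_axis(cfg$axis)
  y <- cfg$contaminant_area * (band_profile(x, 733, 12) +
                                 band_profile(x, 1440, 18))
  spectrum(x, y)
}

#' Generate a seeded synthetic interlaboratory collection
#'
#' Emits one [sers_dataset()] per method x laboratory, with 3 (colloidal)
#' or 9 (solid) replicate spectra per sample, following the intensity model
#' documented in [synth_config()]. Generation is fully deterministic given
#' the configuration (including its `seed`); the caller's RNG state is left
#' untouched.
#'
#' @param cfg a [synth_config()].
#' @return list with `datasets` (list of [sers_dataset()]) and `truth`, a
#'   record of the simulated ground truth: per-dataset lab gains and
#'   contamination flags, a per-spectrum table of true band areas, the true
#'   test concentrations, and the configuration echo.
#' @export
generate_collection <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "sers_synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)

  x <- expand_axis(cfg$axis)
  base <- synth_baseline(cfg, x)
  mat <- synth_matrix(cfg, x)
  profile <- band_profile(x, cfg$band_center, cfg$band_fwhm)
  contam <- contaminant_reference(cfg)$intensity
  win <- x >= 715 & x <= 750
  win_frac <- trapz(x[win], profile[win])

  label <- function(prefix, n, from = 1L) {
    if (n == 0L) return(character())
    paste0(prefix, seq_len(n) - 1L + from)
  }
  cal_levels <- label("C", length(cfg$cal_concentrations), from = 0L)
  test_levels <- label("X", length(cfg$test_concentrations))
  labs <- sprintf("P%02d", seq_len(cfg$labs_per_method))

  datasets <- list()
  truth_rows <- list()
  gains <- list()
  contaminated <- list()

  for (mcode in cfg$methods) {
    n_rep <- expected_replicates(mcode)
    for (lab in labs) {
      g <- stats::rnorm(1L, 1, cfg$lab_gain_sd)
      is_contam <- stats::runif(1L) < cfg$contaminant_prob
      key <- paste(lab, mcode)
      gains[[key]] <- g
      contaminated[[key]] <- is_contam
      make_one <- function(role, level, conc, rep_i) {
        delta <- stats::rnorm(1L, 0, cfg$replicate_sd)
        A <- band_amplitude(cfg, conc)
        clean <- base + g * (A * (1 + delta) * profile + mat)
        if (is_contam) clean <- clean + contam
        sdv <- cfg$noise_sd_additive + cfg$noise_sd_proportional * A
        y <- clean + stats::rnorm(length(x), 0, sdv)
        meta <- spectrum_meta(lab, mcode, role, level, conc, rep_i)
        truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
          lab_id = lab, method_id = mcode, role = role, level_id = level,
          replicate_id = rep_i, concentration = conc, lab_gain = g,
          replicate_delta = delta,
          true_band_area = g * A * (1 + delta) * win_frac,
          stringsAsFactors = FALSE)
        spectrum(x, y, meta = meta)
      }
      cal <- list(); test <- list()
      for (i in seq_along(cfg$cal_concentrations))
        for (r in seq_len(n_rep))
          cal[[length(cal) + 1L]] <- make_one("calibration", cal_levels[i],
                                              cfg$cal_concentrations[i], r)
      for (i in seq_along(cfg$test_concentrations))
        for (r in seq_len(n_rep))
          test[[length(test) + 1L]] <- make_one("test", test_levels[i],
                                                cfg$test_concentrations[i], r)
      ds <- sers_dataset(lab, mcode, cal, test,
                         provenance = sprintf("synthetic (seed %d)", cfg$seed))
      datasets[[length(datasets) + 1L]] <- ds
    }
  }
  truth <- list(
    lab_gain = unlist(gains),
    contaminated = unlist(contaminated),
    spectra = do.call(rbind, truth_rows),
    test_concentrations = stats::setNames(cfg$test_concentrations,
                                          test_levels),
    cal_concentrations = stats::setNames(cfg$cal_concentrations, cal_levels),
    band_window_fraction = win_frac,
    config = cfg)
  list(datasets = datasets, truth = truth)
}

#' Write a collection to disk as text spectra plus a manifest
#'
#' Writes one two-column CSV per spectrum, a `manifest.csv` compatible with
#' [load_ils_collection()], and (optionally) the truth record as JSON.
#'
#' @param datasets list of [sers_dataset()]s.
#' @param dir output directory (created if needed).
#' @param truth optional truth record from [generate_collection()].
#' @return the manifest data frame, invisibly.
#' @export
write_ils_collection <- function(datasets, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ds in datasets) {
    for (s in dataset_spectra(ds)) {
      m <- s$meta
      fname <- sprintf("%s_%s_%s_%s_r%d.csv", m$lab_id,
                       gsub("@", "-", format(m$method)), m$role,
                       m$level_id, m$replicate_id)
      write_spectrum_table(s, file.path(dir, fname))
      rows[[length(rows) + 1L]] <- data.frame(
        file = fname, lab = m$lab_id, method = format(m$method),
        role = m$role, level = m$level_id, replicate = m$replicate_id,
        concentration_uM = m$concentration, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(truth)) {
    tr <- truth; tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(manifest)
}
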