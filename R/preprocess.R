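#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing of the intensity trace; the
#' wavenumber axis is unchanged. Polynomials up to `polyorder` are
#' reproduced exactly, so constant and straight-line spectra pass through
#' untouched.
#'
#' @param s a [spectrum()].
#' @param window odd window width in points, greater than `polyorder`.
#' @param polyorder polynomial order of the local fit.
#' @return the smoothed [spectrum()].
#' @export
smooth_spectrum <- function(s, window = 9L, polyorder = 2L) {
  stopifnot(inherits(s, "sers_spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop_serscal("smoothing window must be odd")
  if (polyorder >= window) stop_serscal("polyorder must be < window")
  if (window > length(s$wavenumber))
    stop_serscal("smoothing window exceeds spectrum length")
  set_intensity(s, signal::sgolayfilt(s$intensity, p = polyorder, n = window))
}

#' Resample a spectrum onto a target axis
#'
#' Linear interpolation onto a new wavenumber grid. Extrapolation is
#' refused: the target axis must lie within the source axis range.
#'
#' @param s a [spectrum()].
#' @param target_axis numeric vector of wavenumbers, or a `c(start, stop,
#'   step)` triple.
#' @return the resampled [spectrum()].
#' @export
resample_spectrum <- function(s, target_axis) {
  stopifnot(inherits(s, "sers_spectrum"))
  axis <- expand_axis(target_axis)
  if (min(axis) < min(s$wavenumber) || max(axis) > max(s$wavenumber))
    stop_serscal(sprintf(
      "target axis [%g, %g] extends beyond source range [%g, %g]",
      min(axis), max(axis), min(s$wavenumber), max(s$wavenumber)))
  y <- stats::approx(s$wavenumber, s$intensity, xout = axis)$y
  spectrum(axis, y, meta = s$meta)
}

# Accept either an explicit axis vector or a (start, stop, step) triple.
expand_axis <- function(target_axis) {
  if (length(target_axis) == 3L && target_axis[3] > 0 &&
      target_axis[2] > target_axis[1]) {
    seq(target_axis[1], target_axis[2], by = target_axis[3])
  } else {
    as.numeric(target_axis)
  }
}

#' Crop a spectrum to a closed wavenumber window
#'
#' @param s a [spectrum()].
#' @param lo,hi window limits in 1/cm; points with `lo <= wavenumber <= hi`
#'   are retained.
#' @return the cropped [spectrum()].
#' @export
crop_spectrum <- function(s, lo, hi) {
  stopifnot(inherits(s, "sers_spectrum"))
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (sum(keep) < 2L)
    stop_serscal(sprintf("crop window [%g, %g] leaves fewer than 2 points", lo, hi))
  spectrum(s$wavenumber[keep], s$intensity[keep], meta = s$meta)
}

#' Baseline estimation and subtraction
#'
#' Three standard chemometric baseline models are provided. `"als"` is
#' asymmetric least squares (Whittaker smoothing with asymmetric weights):
#' the baseline minimizes a weighted squared misfit plus `lambda` times the
#' squared second differences, with weight `p` on points above the baseline
#' and `1 - p` below, iterated to convergence of the weight pattern.
#' `"aspoly"` uses the same asymmetric reweighting but fits a polynomial of
#' the given `degree` instead of a Whittaker smoother, so the estimated
#' baseline is exactly a polynomial. `"modpoly"` is iterative polynomial
#' fitting in which the working trace is clipped to the fitted polynomial
#' each round, driving the fit under the peaks.
#'
#' @param s a [spectrum()].
#' @param method `"als"` (default), `"aspoly"` or `"modpoly"`.
#' @param lambda ALS smoothness penalty (default 1e5).
#' @param p asymmetry weight for points above the baseline (default 0.01;
#'   used by `"als"` and `"aspoly"`).
#' @param degree polynomial degree for `"aspoly"`/`"modpoly"` (default 4).
#' @param max_iter iteration cap (default 50).
#' @param tol relative convergence tolerance for `"modpoly"`.
#' @return list with `corrected` (signal minus baseline) and `baseline`,
#'   both [spectrum()]s on the input axis.
#' @export
baseline_correct <- function(s, method = c("als", "aspoly", "modpoly"),
                             lambda = 1e5, p = 0.01, degree = 4L,
                             max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(s, "sers_spectrum"))
  method <- match.arg(method)
  z <- switch(method,
              als = als_baseline(s$intensity, lambda = lambda, p = p,
                                 max_iter = max_iter),
              aspoly = {
                w <- aspoly_weights(s$wavenumber, s$intensity, degree = degree,
                                    p = p, max_iter = max_iter)
                aspoly_apply(s$wavenumber, s$intensity, w, degree = degree)
              },
              modpoly = modpoly_baseline(s$wavenumber, s$intensity,
                                         degree = degree,
                                         max_iter = max_iter, tol = tol))
  list(corrected = set_intensity(s, s$intensity - z),
       baseline = set_intensity(s, z))
}

# Converge the asymmetric 0/1-type weight pattern of a polynomial baseline
# on one trace: weight p above the current fit, 1 - p below.
aspoly_weights <- function(x, y, degree = 4L, p = 0.01, max_iter = 50L) {
  X <- cbind(1, stats::poly(scale_axis(x), degree = degree, raw = TRUE))
  w <- rep(1, length(y))
  for (iter in seq_len(max_iter)) {
    cf <- stats::lm.wfit(X, y, w)$coefficients
    cf[is.na(cf)] <- 0
    fit <- as.numeric(X %*% cf)
    w_new <- ifelse(y > fit, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  w
}

# Weighted polynomial baseline for a trace under a fixed weight vector.
# With fixed weights this is a linear projection of the trace onto the
# polynomial span, a property run_preprocess exploits by sharing one weight
# pattern across a whole dataset.
aspoly_apply <- function(x, y, w, degree = 4L) {
  X <- cbind(1, stats::poly(scale_axis(x), degree = degree, raw = TRUE))
  cf <- stats::lm.wfit(X, y, w)$coefficients
  cf[is.na(cf)] <- 0
  as.numeric(X %*% cf)
}

# Whittaker smoother with asymmetric weights (Eilers-style ALS). The linear
# system (W + lambda * D'D) z = W y is pentadiagonal; Matrix's sparse
# Cholesky keeps each solve cheap. Iteration stops as soon as the weight
# pattern repeats, which for clean spectra happens within a few rounds.
als_baseline <- function(y, lambda = 1e5, p = 0.01, max_iter = 50L) {
  n <- length(y)
  if (n < 4L) return(rep(min(y), n))
  i <- seq_len(n - 2L)
  D <- Matrix::sparseMatrix(i = c(i, i, i), j = c(i, i + 1L, i + 2L),
                            x = rep(c(1, -2, 1), each = n - 2L),
                            dims = c(n - 2L, n))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  for (iter in seq_len(max_iter)) {
    A <- P + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

# Iterative polynomial baseline ("modpoly"): repeatedly fit a polynomial
# and clip the working trace to it.
modpoly_baseline <- function(x, y, degree = 4L, max_iter = 50L, tol = 1e-8) {
  xs <- scale_axis(x)
  X <- stats::poly(xs, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  work <- y
  scale <- max(abs(y), 1e-300)
  fit <- rep(0, length(y))
  for (iter in seq_len(max_iter)) {
    cf <- stats::lm.fit(X, work)$coefficients
    cf[is.na(cf)] <- 0
    fit_new <- as.numeric(X %*% cf)
    delta <- max(abs(fit_new - fit)) / scale
    fit <- fit_new
    work <- pmin(work, fit)
    if (delta < tol && iter > 1L) break
  }
  fit
}

scale_axis <- function(x) {
  m <- mean(range(x)); h <- diff(range(x)) / 2
  if (h == 0) h <- 1
  (x - m) / h
}

#' Extended multiplicative signal correction
#'
#' Least-squares decomposition of a spectrum into a multiple of a reference
#' spectrum plus a smooth polynomial background:
#' `s(v) ~ b * ref(v) + sum_k a_k * v^k`. The corrected spectrum is
#' `(s - background) / b`, which removes the additive background and the
#' multiplicative gain relative to the reference.
#'
#' The fit can exclude a wavenumber window (typically the analyte band plus
#' a guard margin) so that the gain `b` is estimated from
#' concentration-invariant spectral content only; the correction itself is
#' always applied over the full axis. Without such a mask, a spectrum whose
#' only feature is the analyte band would have its concentration signal
#' absorbed into `b`.
#'
#' Internally the polynomial is fitted on a centered, scaled axis for
#' numerical stability; the returned `poly_coef` are re-expanded monomial
#' coefficients `a_0..a_d` in the raw wavenumber variable.
#'
#' @param s a [spectrum()].
#' @param reference a [spectrum()] on the same axis, not constant.
#' @param poly_degree background polynomial degree (default 2).
#' @param exclude optional `c(lo, hi)` window (1/cm) excluded from the fit.
#' @param b_tol smallest admissible `|b|`; below it the spectrum is deemed
#'   orthogonal to the reference and an error is raised.
#' @return list with `corrected` (a [spectrum()]), `b` (gain),
#'   `poly_coef` (`a_0..a_d`), and `background` (fitted polynomial values).
#' @export
emsc <- function(s, reference, poly_degree = 2L, exclude = NULL,
                 b_tol = 1e-8) {
  stopifnot(inherits(s, "sers_spectrum"), inherits(reference, "sers_spectrum"))
  if (length(s$wavenumber) != length(reference$wavenumber) ||
      any(abs(s$wavenumber - reference$wavenumber) > 1e-9))
    stop_serscal("spectrum and EMSC reference must share one axis")
  if (stats::sd(reference$intensity) == 0)
    stop_serscal("EMSC reference must not be constant")
  x <- s$wavenumber
  xs <- scale_axis(x)
  Xp <- vapply(0:poly_degree, function(k) xs^k, numeric(length(xs)))
  X <- cbind(ref = reference$intensity, Xp)
  mask <- rep(TRUE, length(x))
  if (!is.null(exclude))
    mask <- !(x >= exclude[1] & x <= exclude[2])
  if (sum(mask) < poly_degree + 3L)
    stop_serscal("too few points outside the EMSC exclusion window")
  cf <- stats::lm.fit(X[mask, , drop = FALSE], s$intensity[mask])$coefficients
  if (anyNA(cf))
    stop_serscal("EMSC design is rank-deficient (reference collinear with polynomial)")
  b <- cf[[1L]]
  ref_scale <- max(abs(reference$intensity))
  sig_scale <- max(abs(s$intensity), 1e-300)
  if (abs(b) * ref_scale < b_tol * sig_scale)
    stop_serscal("EMSC gain |b| below tolerance (spectrum orthogonal to reference)")
  a_scaled <- cf[-1L]
  background <- as.numeric(Xp %*% a_scaled)
  corrected <- set_intensity(s, (s$intensity - background) / b)
  list(corrected = corrected, b = b,
       poly_coef = expand_poly_coef(a_scaled, x),
       background = background)
}

# Convert coefficients of sum_k c_k ((v - m)/h)^k into raw monomial
# coefficients a_j of sum_j a_j v^j via binomial expansion.
expand_poly_coef <- function(c_scaled, x) {
  m <- mean(range(x)); h <- diff(range(x)) / 2
  if (h == 0) h <- 1
  d <- length(c_scaled) - 1L
  a <- numeric(d + 1L)
  for (k in 0:d) {
    ck <- c_scaled[k + 1L] / h^k
    for (j in 0:k) {
      a[j + 1L] <- a[j + 1L] + ck * choose(k, j) * (-m)^(k - j)
    }
  }
  names(a) <- paste0("a", 0:d)
  a
}

#' Preprocessing configuration
#'
#' Bundles the parameters of the preprocessing chain applied by
#' [run_preprocess()]: Savitzky-Golay smoothing, resampling to a common
#' axis, spectral-range selection, baseline correction, and EMSC
#' normalization. Defaults follow common chemometrics practice; every value
#' is exposed so a study-specific protocol can be substituted verbatim.
#'
#' @param smooth_window,smooth_polyorder Savitzky-Golay window (odd points)
#'   and polynomial order.
#' @param target_axis `c(start, stop, step)` in 1/cm, or `NULL` to use a
#'   1 1/cm grid over the intersection of all axes in the dataset.
#' @param range_keep `c(lo, hi)` retained spectral range, 1/cm.
#' @param baseline_method `"aspoly"` (default), `"als"` or `"modpoly"`.
#' @param baseline_params list of parameters passed to the baseline stage.
#' @param baseline_shared share one baseline weight pattern, converged on
#'   the pointwise median of the dataset's calibration spectra, across all
#'   spectra of the dataset (`"aspoly"` and `"als"` only). A shared pattern
#'   makes the baseline stage a fixed linear operator, so every spectrum of
#'   the dataset is treated identically and no concentration-dependent
#'   baseline distortion is introduced.
#' @param emsc_poly_degree EMSC background polynomial degree; keep it at
#'   least as large as the `"aspoly"` baseline degree so any polynomial
#'   residue of the baseline stage is absorbed exactly.
#' @param emsc_reference `"median_calibration"` (pointwise median of the
#'   dataset's own calibration spectra, scaled to unit mean absolute
#'   intensity over the fit region) or a supplied [spectrum()].
#' @param emsc_exclude window (1/cm) excluded from the EMSC fit; defaults to
#'   the analyte band plus a 65 1/cm guard on each side, wide enough that
#'   band tails and smoothing spill-over cannot bias the gain estimate.
#' @param band_window analyte integration window, 1/cm.
#' @return an object of class `sers_preprocess_config` (a validated list).
#' @export
preprocess_config <- function(smooth_window = 9L, smooth_polyorder = 2L,
                              target_axis = NULL, range_keep = c(400, 1800),
                              baseline_method = "aspoly",
                              baseline_params = list(),
                              baseline_shared = TRUE,
                              emsc_poly_degree = 4L,
                              emsc_reference = "median_calibration",
                              emsc_exclude = NULL,
                              band_window = c(715, 750)) {
  if (smooth_window %% 2L == 0L || smooth_polyorder >= smooth_window)
    stop_serscal("need odd smooth_window > smooth_polyorder")
  if (emsc_poly_degree < 0L) stop_serscal("emsc_poly_degree must be >= 0")
  if (range_keep[2] <= range_keep[1]) stop_serscal("range_keep must be increasing")
  defaults <- switch(baseline_method,
                     aspoly = list(p = 0.01, degree = 4L, max_iter = 50L),
                     als = list(lambda = 1e5, p = 0.01, max_iter = 50L),
                     modpoly = list(degree = 4L, max_iter = 50L),
                     stop_serscal("unknown baseline method"))
  baseline_params <- utils::modifyList(defaults, baseline_params)
  if (is.null(emsc_exclude))
    emsc_exclude <- c(band_window[1] - 65, band_window[2] + 65)
  structure(list(smooth_window = as.integer(smooth_window),
                 smooth_polyorder = as.integer(smooth_polyorder),
                 target_axis = target_axis, range_keep = range_keep,
                 baseline_method = baseline_method,
                 baseline_params = baseline_params,
                 baseline_shared = isTRUE(baseline_shared),
                 emsc_poly_degree = as.integer(emsc_poly_degree),
                 emsc_reference = emsc_reference,
                 emsc_exclude = emsc_exclude,
                 band_window = band_window),
            class = "sers_preprocess_config")
}

#' Run the preprocessing chain on a dataset
#'
#' Applies, in order: smoothing, resampling to the common axis, range
#' selection, baseline correction, and EMSC normalization against the
#' dataset's reference spectrum. Metadata are never altered; each stage
#' appends a provenance line.
#'
#' When `emsc_reference = "median_calibration"` the reference is the
#' pointwise median of the dataset's own (already smoothed, resampled,
#' cropped and baseline-corrected) calibration spectra, scaled to unit mean
#' absolute intensity over the EMSC fit region. The scaling makes the
#' corrected spectra gain-free, so spectra of equal concentration become
#' superimposable across laboratories.
#'
#' @param ds a [sers_dataset()] (ideally one that passed
#'   [integrity_check()]).
#' @param cfg a [preprocess_config()].
#' @return the preprocessed [sers_dataset()].
#' @export
run_preprocess <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "sers_dataset"),
            inherits(cfg, "sers_preprocess_config"))
  specs <- dataset_spectra(ds)
  # common axis: explicit, or 1 1/cm over the intersection of all axes
  if (is.null(cfg$target_axis)) {
    lo <- max(vapply(specs, function(s) min(s$wavenumber), 0))
    hi <- min(vapply(specs, function(s) max(s$wavenumber), 0))
    axis <- seq(ceiling(lo), floor(hi), by = 1)
  } else {
    axis <- expand_axis(cfg$target_axis)
  }
  stage0 <- lapply(specs, function(s) {
    s <- smooth_spectrum(s, cfg$smooth_window, cfg$smooth_polyorder)
    s <- resample_spectrum(s, axis)
    lo <- max(cfg$range_keep[1], min(axis))
    hi <- min(cfg$range_keep[2], max(axis))
    crop_spectrum(s, lo, hi)
  })
  n_cal <- length(ds$calibration)
  stage1 <- apply_baseline(stage0, n_cal, cfg)
  if (inherits(cfg$emsc_reference, "sers_spectrum")) {
    ref <- resample_spectrum(cfg$emsc_reference, stage1[[1L]]$wavenumber)
  } else if (identical(cfg$emsc_reference, "median_calibration")) {
    cal_mat <- vapply(stage1[seq_len(n_cal)], function(s) s$intensity,
                      numeric(length(stage1[[1L]]$intensity)))
    ref <- spectrum(stage1[[1L]]$wavenumber,
                    apply(cal_mat, 1L, stats::median))
    fit_mask <- !(ref$wavenumber >= cfg$emsc_exclude[1] &
                    ref$wavenumber <= cfg$emsc_exclude[2])
    scale <- mean(abs(ref$intensity[fit_mask]))
    if (scale <= 0)
      stop_serscal("EMSC reference has no intensity outside the exclusion window")
    ref <- set_intensity(ref, ref$intensity / scale)
  } else {
    stop_serscal("unknown emsc_reference policy")
  }
  out <- lapply(stage1, function(s) {
    emsc(s, ref, poly_degree = cfg$emsc_poly_degree,
         exclude = cfg$emsc_exclude)$corrected
  })
  ds$calibration <- out[seq_len(n_cal)]
  ds$test <- out[seq_len(length(out) - n_cal) + n_cal]
  ds <- log_provenance(ds, sprintf(
    "preprocess: sgolay(%d,%d) -> resample[%g:%g:1] -> crop[%g,%g] -> %s%s -> emsc(deg %d, exclude [%g,%g], ref %s)",
    cfg$smooth_window, cfg$smooth_polyorder, min(axis), max(axis),
    cfg$range_keep[1], cfg$range_keep[2], cfg$baseline_method,
    if (cfg$baseline_shared && cfg$baseline_method != "modpoly")
      "(shared weights)" else "",
    cfg$emsc_poly_degree, cfg$emsc_exclude[1], cfg$emsc_exclude[2],
    if (inherits(cfg$emsc_reference, "sers_spectrum")) "supplied" else cfg$emsc_reference))
  ds
}

# Baseline stage of run_preprocess. With baseline_shared, the asymmetric
# weight pattern is converged once on the pointwise median of the
# calibration spectra and then applied to every spectrum, so the stage acts
# as one fixed linear operator on the whole dataset.
apply_baseline <- function(stage0, n_cal, cfg) {
  pars <- cfg$baseline_params
  if (!cfg$baseline_shared || cfg$baseline_method == "modpoly") {
    return(lapply(stage0, function(s)
      do.call(baseline_correct,
              c(list(s = s, method = cfg$baseline_method), pars))$corrected))
  }
  x <- stage0[[1L]]$wavenumber
  med <- apply(vapply(stage0[seq_len(n_cal)], function(s) s$intensity,
                      numeric(length(x))), 1L, stats::median)
  if (cfg$baseline_method == "aspoly") {
    w <- aspoly_weights(x, med, degree = pars$degree, p = pars$p,
                        max_iter = pars$max_iter)
    lapply(stage0, function(s)
      set_intensity(s, s$intensity -
                      aspoly_apply(x, s$intensity, w, degree = pars$degree)))
  } else {  # als with shared weights
    n <- length(x)
    i <- seq_len(n - 2L)
    D <- Matrix::sparseMatrix(i = c(i, i, i), j = c(i, i + 1L, i + 2L),
                              x = rep(c(1, -2, 1), each = n - 2L),
                              dims = c(n - 2L, n))
    P <- pars$lambda * Matrix::crossprod(D)
    w <- rep(1, n)
    for (iter in seq_len(pars$max_iter)) {
      z <- as.numeric(Matrix::solve(P + Matrix::Diagonal(n, w), w * med))
      w_new <- ifelse(med > z, pars$p, 1 - pars$p)
      if (identical(w_new, w)) break
      w <- w_new
    }
    A <- P + Matrix::Diagonal(n, w)
    lapply(stage0, function(s)
      set_intensity(s, s$intensity -
                      as.numeric(Matrix::solve(A, w * s$intensity))))
  }
}
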