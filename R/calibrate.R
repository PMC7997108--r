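#' Integrated band area
#'
#' Trapezoidal integral of the intensity over a closed wavenumber window,
#' by default the adenine ring-breathing band at 715-750 1/cm used as the
#' quantitative SERS response.
#'
#' @param s a (preprocessed) [spectrum()].
#' @param lo,hi integration window limits, 1/cm.
#' @return numeric area (intensity x 1/cm).
#' @export
band_area <- function(s, lo = 715, hi = 750) {
  stopifnot(inherits(s, "sers_spectrum"))
  if (min(s$wavenumber) > lo || max(s$wavenumber) < hi)
    stop_serscal(sprintf("axis does not cover the band window [%g, %g]", lo, hi))
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  trapz(s$wavenumber[keep], s$intensity[keep])
}

#' Mean band area over the replicates of one sample
#'
#' @param spectra list of replicate [spectrum()]s of one sample.
#' @param lo,hi integration window, 1/cm.
#' @return arithmetic mean of the replicate band areas, with the replicate
#'   count attached as attribute `n_replicates`.
#' @export
sample_response <- function(spectra, lo = 715, hi = 750) {
  if (length(spectra) < 1L) stop_serscal("need at least one replicate")
  areas <- vapply(spectra, band_area, 0, lo = lo, hi = hi)
  structure(mean(areas), n_replicates = length(areas))
}

#' Inverse least-squares calibration
#'
#' Fits the inverse univariate calibration `concentration = b0 + b1 * area`
#' by ordinary least squares: regressing concentration on the band-area
#' response means predictions for unknowns come straight from the fitted
#' line. The fit carries the system-suitability statistics used to gate a
#' calibration before prediction: the curve is `suitable` when
#' `r^2 >= 0.6` and the overall-regression F-test p-value is `<= 0.01`;
#' failing curves carry machine-readable reason codes
#' (`"r2_below_threshold"`, `"f_test_not_significant"`).
#'
#' @param area numeric band areas of the calibration standards, or a
#'   two-column data frame/matrix of (area, concentration) pairs.
#' @param concentration reference concentrations (µM), matching `area`.
#' @param r2_min,f_alpha suitability thresholds (defaults 0.6 and 0.01).
#' @return an object of class `sers_calibration` with components
#'   `coefficients` (b0, b1), `r_squared`, `f_statistic`, `f_pvalue`,
#'   `n_points`, `cal_range`, `suitable`, `reasons`, `fitted`, `residuals`
#'   and the input `data`.
#' @seealso [predict.sers_calibration()], [run_experiment()]
#' @examples
#' fit <- fit_inverse_calibration(c(1, 2, 3), c(10, 20, 30))
#' coef(fit)          # b0 = 0, b1 = 10
#' predict(fit, 2.5)  # 25
#' @export
fit_inverse_calibration <- function(area, concentration = NULL,
                                    r2_min = 0.6, f_alpha = 0.01) {
  if (is.null(concentration)) {
    pairs <- as.data.frame(area)
    area <- pairs[[1L]]; concentration <- pairs[[2L]]
  }
  area <- as.numeric(area); concentration <- as.numeric(concentration)
  if (length(area) != length(concentration))
    stop_serscal("area and concentration must have equal length")
  n <- length(area)
  if (length(unique(area)) < 3L)
    stop_serscal("need at least 3 distinct area values (degenerate design)")
  fit <- stats::lm(concentration ~ area)
  # summary.lm warns on numerically perfect fits, which synthetic
  # noise-free calibrations legitimately produce
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  fs <- sm$fstatistic
  fp <- stats::pf(fs[[1L]], fs[[2L]], fs[[3L]], lower.tail = FALSE)
  reasons <- character()
  if (r2 < r2_min) reasons <- c(reasons, "r2_below_threshold")
  if (fp > f_alpha) reasons <- c(reasons, "f_test_not_significant")
  structure(list(
    coefficients = c(b0 = unname(stats::coef(fit)[1L]),
                     b1 = unname(stats::coef(fit)[2L])),
    r_squared = r2, f_statistic = fs[[1L]], f_pvalue = fp,
    n_points = n,
    cal_range = range(concentration),
    suitable = length(reasons) == 0L, reasons = reasons,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    data = data.frame(area = area, concentration = concentration),
    thresholds = c(r2_min = r2_min, f_alpha = f_alpha)),
    class = "sers_calibration")
}

#' @export
coef.sers_calibration <- function(object, ...) object$coefficients

#' @export
residuals.sers_calibration <- function(object, ...) object$residuals

#' Predict concentrations from band areas
#'
#' Applies the inverse calibration line `b0 + b1 * area`. Predictions are
#' never clipped: values outside the calibration range (including negative
#' concentrations) are returned as-is, flagged through the
#' `out_of_range` attribute. An unsuitable model refuses to predict unless
#' `override_suitability = TRUE` (diagnostic use).
#'
#' @param object a [fit_inverse_calibration()] model.
#' @param area numeric band areas.
#' @param override_suitability predict even from an unsuitable model.
#' @param ... unused.
#' @return predicted concentrations (µM) with attribute `out_of_range`.
#' @export
predict.sers_calibration <- function(object, area,
                                     override_suitability = FALSE, ...) {
  if (!object$suitable && !override_suitability)
    stop_serscal(paste("calibration not suitable for prediction:",
                       paste(object$reasons, collapse = ", ")))
  pred <- object$coefficients[["b0"]] + object$coefficients[["b1"]] * area
  structure(pred,
            out_of_range = pred < object$cal_range[1L] |
              pred > object$cal_range[2L])
}

#' @export
print.sers_calibration <- function(x, ...) {
  cat("Inverse least-squares SERS calibration\n")
  cat(sprintf("  c = %.6g + %.6g * area   (n = %d standards)\n",
              x$coefficients[["b0"]], x$coefficients[["b1"]], x$n_points))
  cat(sprintf("  r^2 = %.4f, F = %.3g (p = %.3g)\n",
              x$r_squared, x$f_statistic, x$f_pvalue))
  cat(sprintf("  suitable: %s%s\n", x$suitable,
              if (x$suitable) "" else paste0(" (",
                                             paste(x$reasons, collapse = ", "), ")")))
  invisible(x)
}

#' @export
summary.sers_calibration <- function(object, ...) {
  structure(list(model = object), class = "summary.sers_calibration")
}

#' @export
print.summary.sers_calibration <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  calibration range: %.4g - %.4g uM\n",
              m$cal_range[1L], m$cal_range[2L]))
  cat(sprintf("  residual SD on standards: %.4g uM\n",
              stats::sd(m$residuals)))
  cat(sprintf("  suitability thresholds: r^2 >= %g, F p <= %g\n",
              m$thresholds[["r2_min"]], m$thresholds[["f_alpha"]]))
  invisible(x)
}

#' @export
plot.sers_calibration <- function(x, ...) {
  d <- x$data
  graphics::plot(d$area, d$concentration,
                 xlab = "band area (a.u.)", ylab = "concentration (uM)",
                 main = "Inverse SERS calibration", ...)
  graphics::abline(x$coefficients[["b0"]], x$coefficients[["b1"]], lty = 2)
  invisible(x)
}

#' Calibrate one dataset and predict its test samples
#'
#' The single-experiment validation scheme: the calibration spectra of a
#' (preprocessed) dataset are integrated over the analyte window, replicate
#' areas are averaged per sample, an inverse calibration is fitted, and,
#' when the curve passes the suitability gate, each test sample is
#' predicted. A rejected calibration yields zero prediction records and a
#' reason string.
#'
#' @param ds a preprocessed [sers_dataset()].
#' @param band_window integration window, 1/cm.
#' @param replicate_handling `"mean"` (default: one averaged response per
#'   sample) or `"individual"` (every replicate enters the regression).
#' @return list with `model` (a `sers_calibration`), `records` (data frame
#'   of per-test-sample prediction records: lab, method, level, reference,
#'   predicted, residual, out-of-range flag; zero rows when rejected) and
#'   `reason` (`NULL` when accepted).
#' @export
run_experiment <- function(ds, band_window = c(715, 750),
                           replicate_handling = c("mean", "individual")) {
  stopifnot(inherits(ds, "sers_dataset"))
  replicate_handling <- match.arg(replicate_handling)
  lo <- band_window[1]; hi <- band_window[2]
  cal_levels <- split(ds$calibration,
                      vapply(ds$calibration, function(s) s$meta$level_id, ""))
  if (replicate_handling == "mean") {
    a <- vapply(cal_levels, function(g) as.numeric(sample_response(g, lo, hi)), 0)
    cc <- vapply(cal_levels, function(g) g[[1L]]$meta$concentration, 0)
  } else {
    a <- unlist(lapply(cal_levels, function(g)
      vapply(g, band_area, 0, lo = lo, hi = hi)))
    cc <- unlist(lapply(cal_levels, function(g)
      vapply(g, function(s) s$meta$concentration, 0)))
  }
  model <- fit_inverse_calibration(a, cc)
  empty <- data.frame(lab_id = character(), method_id = character(),
                      level_id = character(), reference = numeric(),
                      predicted = numeric(), residual = numeric(),
                      out_of_range = logical(), stringsAsFactors = FALSE)
  if (!model$suitable)
    return(list(model = model, records = empty,
                reason = paste(model$reasons, collapse = ", ")))
  test_levels <- split(ds$test,
                       vapply(ds$test, function(s) s$meta$level_id, ""))
  recs <- lapply(test_levels, function(g) {
    area <- as.numeric(sample_response(g, lo, hi))
    pred <- predict(model, area)
    ref <- g[[1L]]$meta$concentration
    data.frame(lab_id = ds$lab_id, method_id = format(ds$method),
               level_id = g[[1L]]$meta$level_id,
               reference = ref, predicted = as.numeric(pred),
               residual = as.numeric(pred) - ref,
               out_of_range = as.logical(attr(pred, "out_of_range")),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(model = model, records = records, reason = NULL)
}
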