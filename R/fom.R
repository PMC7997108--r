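#' ISO 5725 figures of merit from pooled prediction residuals
#'
#' Decomposes the accuracy of a method's pooled test-set residuals
#' `e_i = predicted - reference` into trueness and precision:
#' \deqn{BIAS = \frac{1}{n}\sum e_i, \quad
#'       RMSEP = \sqrt{\frac{1}{n}\sum e_i^2}, \quad
#'       SEP = \sqrt{\frac{1}{n-1}\sum (e_i - BIAS)^2}.}
#' RMSEP is the total prediction error (accuracy), BIAS the systematic
#' component (trueness), SEP the bias-corrected spread (reproducibility).
#' With these denominators the decomposition
#' `RMSEP^2 = BIAS^2 + SEP^2 * (n-1)/n` is an exact algebraic identity; the
#' familiar approximate form `RMSEP^2 ~ SEP^2 + BIAS^2` follows for large
#' n. Outlying residuals are deliberately not removed.
#'
#' A two-sided one-sample Student's t-test of zero mean residual
#' ([bias_test()]) is attached; the bias is flagged significant at the 99%
#' confidence level.
#'
#' @param residuals numeric vector of prediction residuals (µM, or any
#'   common concentration unit), `n >= 2`.
#' @param alpha significance level of the bias t-test (default 0.01).
#' @return an object of class `sers_fom` with components `n`, `rmsep`,
#'   `sep`, `bias`, `bias_t`, `bias_p`, `bias_significant`; the normalized
#'   slots (`rmsep_norm`, `sep_norm`, `bias_norm`, `inv_sep_norm`,
#'   `quality_class`) are filled by [normalize_foms()].
#' @seealso [normalize_foms()], [bias_test()], [iso_identity_check()]
#' @examples
#' f <- compute_foms(c(1, -1, 1, -1, 0))
#' f$rmsep   # sqrt(0.8)
#' f$sep     # 1
#' @export
compute_foms <- function(residuals, alpha = 0.01) {
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 2L) stop_serscal("need at least 2 residuals")
  if (any(!is.finite(e))) stop_serscal("residuals must be finite")
  bias <- mean(e)
  rmsep <- sqrt(mean(e^2))
  sep <- stats::sd(e)
  bt <- bias_test(e, alpha = alpha)
  structure(list(n = n, rmsep = rmsep, sep = sep, bias = bias,
                 rmsep_norm = NA_real_, sep_norm = NA_real_,
                 bias_norm = NA_real_, inv_sep_norm = NA_real_,
                 quality_class = NA_character_,
                 ref_range = NULL,
                 bias_t = bt$t, bias_p = bt$p,
                 bias_significant = bt$significant, alpha = alpha),
            class = "sers_fom")
}

#' Range-normalize figures of merit and assign a quality class
#'
#' Divides RMSEP, SEP and BIAS by the width of the calibration reference
#' concentration range so that methods calibrated over different analyte
#' ranges can be compared. The reciprocal of the normalized SEP serves as a
#' quality index: `1/SEP > 4` is acceptable for sample screening,
#' `> 10` for quality control, and `> 15` for quantification (strict
#' inequalities).
#'
#' @param f a [compute_foms()] result.
#' @param ref_range `c(min, max)` of the calibration reference
#'   concentrations (µM), `max > min`.
#' @return `f` with the normalized slots filled (stored as fractions, e.g.
#'   0.12 for 12%).
#' @examples
#' f <- normalize_foms(compute_foms(c(4, -5, 6, -5)), c(0, 50))
#' f$sep_norm        # fraction of the range
#' f$quality_class
#' @export
normalize_foms <- function(f, ref_range) {
  stopifnot(inherits(f, "sers_fom"))
  width <- ref_range[2] - ref_range[1]
  if (!is.finite(width) || width <= 0)
    stop_serscal("reference range must have positive width")
  f$rmsep_norm <- f$rmsep / width
  f$sep_norm <- f$sep / width
  f$bias_norm <- f$bias / width
  f$inv_sep_norm <- 1 / f$sep_norm
  f$quality_class <- sep_quality_class(f$inv_sep_norm)
  f$ref_range <- ref_range
  f
}

#' @rdname normalize_foms
#' @param inv_sep 1 / normalized SEP.
#' @export
sep_quality_class <- function(inv_sep) {
  if (!is.finite(inv_sep)) return("quantification")
  if (inv_sep > 15) "quantification"
  else if (inv_sep > 10) "quality-control"
  else if (inv_sep > 4) "screening"
  else "none"
}

#' Student's t-test for systematic bias
#'
#' Two-sided one-sample t-test of mean residual equal to zero, evaluated at
#' the 99% confidence level by default: a significant result means the mean
#' deviation is larger than expected from random noise alone. The
#' degenerate zero-variance case is handled explicitly: a nonzero mean with
#' zero spread is significant with infinite t.
#'
#' @param residuals numeric vector, `n >= 2`.
#' @param alpha significance level (default 0.01).
#' @return list with `t`, `p`, `significant`.
#' @export
bias_test <- function(residuals, alpha = 0.01) {
  e <- as.numeric(residuals)
  if (length(e) < 2L) stop_serscal("need at least 2 residuals")
  if (stats::sd(e) == 0) {
    if (mean(e) == 0) return(list(t = 0, p = 1, significant = FALSE))
    return(list(t = sign(mean(e)) * Inf, p = 0, significant = TRUE))
  }
  ht <- stats::t.test(e, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha)
}

#' Check the exact accuracy decomposition
#'
#' Verifies `rmsep^2 = bias^2 + sep^2 * (n-1)/n`, which is an exact
#' algebraic identity under the denominators used by [compute_foms()]
#' (RMSEP over n, SEP over n-1). Also reports the discrepancy of the
#' approximate large-n form `rmsep^2 ~ sep^2 + bias^2`.
#'
#' @param f a [compute_foms()] result.
#' @param tol relative tolerance (default 1e-12).
#' @return `TRUE`/`FALSE`, with attributes `exact_rel_dev` and
#'   `approx_rel_dev`.
#' @export
iso_identity_check <- function(f, tol = 1e-12) {
  stopifnot(inherits(f, "sers_fom"))
  lhs <- f$rmsep^2
  rhs <- f$bias^2 + f$sep^2 * (f$n - 1) / f$n
  scale <- max(lhs, rhs, .Machine$double.xmin)
  exact_dev <- abs(lhs - rhs) / scale
  approx_dev <- abs(lhs - (f$sep^2 + f$bias^2)) / scale
  structure(exact_dev <= tol,
            exact_rel_dev = exact_dev, approx_rel_dev = approx_dev)
}

#' @export
print.sers_fom <- function(x, ...) {
  cat(sprintf("ISO 5725 figures of merit (n = %d residuals)\n", x$n))
  cat(sprintf("  RMSEP = %.4g   SEP = %.4g   BIAS = %+.4g\n",
              x$rmsep, x$sep, x$bias))
  if (is.finite(x$rmsep_norm)) {
    cat(sprintf("  normalized: RMSEP %s, SEP %s, BIAS %s (of range %.4g-%.4g)\n",
                fom_pct(x$rmsep_norm), fom_pct(x$sep_norm),
                fom_pct(x$bias_norm), x$ref_range[1], x$ref_range[2]))
    cat(sprintf("  1/SEP = %.3g -> class '%s'\n", x$inv_sep_norm,
                x$quality_class))
  }
  cat(sprintf("  bias t = %.3g, p = %.3g (%ssignificant at alpha = %g)\n",
              x$bias_t, x$bias_p, if (x$bias_significant) "" else "not ",
              x$alpha))
  invisible(x)
}

# Whole-percent, half-up rendering used in report tables.
fom_pct <- function(frac) sprintf("%d%%", as.integer(round_half_up(100 * frac)))

# Method-level FoMs when datasets may span different calibration ranges:
# residuals are normalized per record by that record's own calibration
# range before pooling, so the normalized slots (and the bias test, run on
# normalized residuals) are comparable across laboratories; the raw slots
# come from the raw pooled residuals.
pooled_foms <- function(residuals, cal_widths, alpha = 0.01) {
  raw <- compute_foms(residuals, alpha = alpha)
  norm <- compute_foms(residuals / cal_widths, alpha = alpha)
  raw$rmsep_norm <- norm$rmsep
  raw$sep_norm <- norm$sep
  raw$bias_norm <- norm$bias
  raw$inv_sep_norm <- 1 / norm$sep
  raw$quality_class <- sep_quality_class(raw$inv_sep_norm)
  raw$bias_t <- norm$bias_t
  raw$bias_p <- norm$bias_p
  raw$bias_significant <- norm$bias_significant
  raw
}
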