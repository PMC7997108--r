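# Small fixtures built in code; all randomness is locally seeded.

# Compact single-method configuration for fast pipeline tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(methods = "cAg@785", labs_per_method = 2L,
         cal_concentrations = 10^seq(0, 2, length.out = 5),
         test_concentrations = 10^seq(0.25, 1.75, length.out = 5),
         seed = 42L),
    list(...))
  do.call(synth_config, args)
}

# Noise-free variant: deterministic spectra, linear response.
noise_free_config <- function(...) {
  tiny_config(lab_gain_sd = 0, replicate_sd = 0, noise_sd_additive = 0,
              noise_sd_proportional = 0, saturation_K = Inf, ...)
}

# Independent numerical integration of the generator's truncated band
# profile over a window (oracle for area tests; re-derives the profile from
# first principles rather than calling package internals).
oracle_window_fraction <- function(center, fwhm, lo, hi,
                                   axis = seq(400, 1800, by = 1),
                                   support_fwhm = 5) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  p <- 0.5 * stats::dnorm(axis, center, sigma) +
    0.5 * (gamma / pi) / ((axis - center)^2 + gamma^2)
  p[abs(axis - center) > support_fwhm * fwhm] <- 0
  tz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2
  p <- p / tz(axis, p)
  keep <- axis >= lo & axis <= hi
  tz(axis[keep], p[keep])
}

# A 5-point calibration with an exact target r^2, built by adding a
# residual vector orthogonal to the regression space and scaling it.
make_r2_pairs <- function(r2_target) {
  x <- 1:5
  y0 <- 2 * x + 1
  v <- c(1, -1, 0, 1, -1)
  X <- cbind(1, x)
  v <- v - X %*% solve(crossprod(X), crossprod(X, v))  # orthogonalize
  v <- as.numeric(v)
  f <- function(t) {
    y <- y0 + t * v
    suppressWarnings(summary(stats::lm(y ~ x)))$r.squared - r2_target
  }
  t <- stats::uniroot(f, c(0, 50))$root
  data.frame(area = x, concentration = y0 + t * v)
}
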