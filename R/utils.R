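#' Round half away from zero
#'
#' Base [round()] rounds half to even ("banker's rounding"); report tables in
#' collaborative-trial work conventionally round half up, so that 81.25%
#' prints as 81.3%. This helper implements round-half-away-from-zero at a
#' given number of decimal digits.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(81.25, 1)   # 81.3, where round() gives 81.2
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Stop with a consistent error class so callers can test error paths.
stop_serscal <- function(msg, class = "serscal_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
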