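#' SERS method identifiers
#'
#' A SERS "method" is the combination of substrate form (colloidal or solid),
#' plasmonic metal (Ag or Au) and laser excitation wavelength. The canonical
#' short code is e.g. `"cAg@785"` for colloidal silver excited at 785 nm or
#' `"sAu@532"` for a solid gold substrate at 532 nm.
#'
#' By default only the six method codes studied in multi-laboratory SERS
#' trials of adenine are accepted (`cAg@532`, `cAg@785`, `cAu@785`,
#' `sAg@532`, `sAg@785`, `sAu@785`); pass `allowed = NULL` or your own
#' vector of codes to extend the set.
#'
#' @param substrate_form `"colloidal"` or `"solid"`.
#' @param metal `"Ag"` or `"Au"`.
#' @param excitation laser wavelength in nm.
#' @param allowed character vector of acceptable canonical codes, or `NULL`
#'   to accept any well-formed combination.
#' @return an object of class `sers_method`.
#' @examples
#' m <- method_id("colloidal", "Ag", 785)
#' format(m)                 # "cAg@785"
#' parse_method_id("sAu@532")
#' @export
method_id <- function(substrate_form = c("colloidal", "solid"),
                      metal = c("Ag", "Au"),
                      excitation,
                      allowed = default_methods()) {
  substrate_form <- match.arg(substrate_form)
  metal <- match.arg(metal)
  excitation <- as.numeric(excitation)
  if (!is.finite(excitation) || excitation <= 0)
    stop_serscal("excitation wavelength must be a positive number (nm)")
  m <- structure(
    list(substrate_form = substrate_form, metal = metal,
         excitation = excitation),
    class = "sers_method")
  code <- format(m)
  if (!is.null(allowed) && !(code %in% allowed))
    stop_serscal(sprintf(
      "method '%s' is not in the accepted set (%s); pass allowed = NULL to extend",
      code, paste(allowed, collapse = ", ")))
  m
}

#' @rdname method_id
#' @export
default_methods <- function() {
  c("cAg@532", "cAg@785", "cAu@785", "sAg@532", "sAg@785", "sAu@785")
}

#' @rdname method_id
#' @param code canonical method code such as `"cAg@785"`.
#' @export
parse_method_id <- function(code, allowed = default_methods()) {
  if (inherits(code, "sers_method")) return(code)
  code <- as.character(code)
  ok <- grepl("^[cs](Ag|Au)@[0-9]+(\\.[0-9]+)?$", code)
  if (!ok)
    stop_serscal(sprintf("malformed method code '%s' (expected e.g. 'cAg@785')", code))
  form <- if (substr(code, 1L, 1L) == "c") "colloidal" else "solid"
  metal <- substr(code, 2L, 3L)
  excitation <- as.numeric(sub("^..+@", "", code))
  method_id(form, metal, excitation, allowed = allowed)
}

#' @export
format.sers_method <- function(x, ...) {
  sprintf("%s%s@%g", if (x$substrate_form == "colloidal") "c" else "s",
          x$metal, x$excitation)
}

#' @export
print.sers_method <- function(x, ...) {
  cat(sprintf("<SERS method %s: %s %s substrate, %g nm excitation>\n",
              format(x), x$substrate_form, x$metal, x$excitation))
  invisible(x)
}

#' @export
as.character.sers_method <- function(x, ...) format(x)

#' Replicates expected per sample for a method's substrate type
#'
#' The replicate scheme follows the standard operating procedure of
#' collaborative SERS trials: 3 replicates per sample for colloidal
#' substrates (one per colloid batch) and 9 for solid substrates (3 spots on
#' each of 3 substrates).
#'
#' @param method a `sers_method` or canonical code.
#' @return integer replicate count (3 or 9).
#' @export
expected_replicates <- function(method) {
  method <- parse_method_id(method, allowed = NULL)
  if (method$substrate_form == "colloidal") 3L else 9L
}
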