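#' Raman/SERS spectrum container
#'
#' A spectrum is a single wavenumber/intensity trace plus acquisition
#' metadata identifying where it sits in an interlaboratory study: the
#' laboratory, the SERS method, its role (calibration standard or test
#' sample), the concentration level label, the concentration itself (µM;
#' `NA` for blind test samples), and the replicate index.
#'
#' @param wavenumber numeric vector of wavenumbers (1/cm), strictly
#'   increasing (a descending axis is re-sorted with intensities permuted to
#'   match).
#' @param intensity numeric vector of detector counts, same length.
#' @param meta a list as returned by [spectrum_meta()], or `NULL`.
#' @return an object of class `sers_spectrum`.
#' @examples
#' s <- spectrum(400:1800, rep(0, 1401))
#' range(s$wavenumber)
#' @export
spectrum <- function(wavenumber, intensity, meta = NULL) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop_serscal("wavenumber and intensity must have equal length")
  if (length(wavenumber) < 2L)
    stop_serscal("a spectrum needs at least 2 points")
  bad <- which(!is.finite(wavenumber) | !is.finite(intensity))
  if (length(bad))
    stop_serscal(sprintf("non-finite value at row %d", bad[1L]))
  if (anyDuplicated(wavenumber))
    stop_serscal("duplicated wavenumbers in axis")
  o <- order(wavenumber)
  structure(list(wavenumber = wavenumber[o], intensity = intensity[o],
                 meta = meta),
            class = "sers_spectrum")
}

#' @rdname spectrum
#' @param lab_id opaque laboratory label, e.g. `"P01"`.
#' @param method a `sers_method` or canonical code such as `"cAg@785"`.
#' @param role `"calibration"` or `"test"`.
#' @param level_id concentration-level label (`"C0"`..`"C8"` style for
#'   calibration, `"X1"`..`"X5"` style for test samples).
#' @param concentration concentration in µM; must be known for calibration
#'   spectra, may be `NA` for blind test samples.
#' @param replicate_id integer replicate index, `>= 1`.
#' @export
spectrum_meta <- function(lab_id, method, role = c("calibration", "test"),
                          level_id, concentration = NA_real_,
                          replicate_id = 1L) {
  role <- match.arg(role)
  concentration <- as.numeric(concentration)
  if (role == "calibration" && !is.finite(concentration))
    stop_serscal("calibration spectra must carry a known concentration")
  if (is.finite(concentration) && concentration < 0)
    stop_serscal("concentration must be >= 0")
  replicate_id <- as.integer(replicate_id)
  if (is.na(replicate_id) || replicate_id < 1L)
    stop_serscal("replicate_id must be an integer >= 1")
  list(lab_id = as.character(lab_id),
       method = parse_method_id(method, allowed = NULL),
       role = role,
       level_id = as.character(level_id),
       concentration = concentration,
       replicate_id = replicate_id)
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<SERS spectrum: %d points, %.1f-%.1f 1/cm", length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  if (!is.null(x$meta))
    cat(sprintf("; %s %s %s %s rep %d",
                x$meta$lab_id, format(x$meta$method), x$meta$role,
                x$meta$level_id, x$meta$replicate_id))
  cat(">\n")
  invisible(x)
}

#' @export
length.sers_spectrum <- function(x) length(x$wavenumber)

# Replace intensities, keeping axis and metadata.
set_intensity <- function(s, intensity) {
  s$intensity <- as.numeric(intensity)
  stopifnot(length(s$intensity) == length(s$wavenumber))
  s
}

#' Read a two-column spectrum table
#'
#' Reads a plain-text table of (wavenumber, intensity) pairs. The delimiter
#' is auto-detected among comma, tab, semicolon and whitespace; lines
#' starting with `#` are treated as comments. A descending axis is re-sorted
#' ascending with intensities permuted accordingly.
#'
#' @param path path to the text file.
#' @param meta optional [spectrum_meta()] attached to the result.
#' @return a [spectrum()].
#' @export
read_spectrum_table <- function(path, meta = NULL) {
  if (!file.exists(path)) stop_serscal(sprintf("cannot read file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L)
    stop_serscal(sprintf("'%s': fewer than 2 data rows", path))
  # delimiter: first candidate that splits every row into >= 2 fields
  delims <- c(",", "\t", ";", "\\s+")
  fields <- NULL
  for (d in delims) {
    f <- strsplit(trimws(lines), d)
    if (all(vapply(f, length, 1L) >= 2L)) { fields <- f; break }
  }
  if (is.null(fields))
    stop_serscal(sprintf("'%s': could not detect a two-column layout", path))
  wn <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(wn) | is.na(it) | !is.finite(wn) | !is.finite(it))
  if (length(bad))
    stop_serscal(sprintf("'%s': non-finite value at row %d", path, bad[1L]))
  spectrum(wn, it, meta = meta)
}

#' Write a spectrum as a two-column CSV
#'
#' Values are written at full double precision so that a read/write
#' round-trip reproduces the spectrum exactly.
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(s, path) {
  stopifnot(inherits(s, "sers_spectrum"))
  lines <- paste(sprintf("%.17g", s$wavenumber),
                 sprintf("%.17g", s$intensity), sep = ",")
  writeLines(c("# wavenumber_cm-1,intensity", lines), path)
  invisible(path)
}
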