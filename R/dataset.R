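#' One laboratory x method bundle of calibration and test spectra
#'
#' A dataset is the unit of analysis of the interlaboratory pipeline: all
#' spectra acquired by one laboratory with one SERS method, split into the
#' calibration set (known concentrations, used to build the inverse
#' regression) and the test set (used to validate it).
#'
#' @param lab_id laboratory label.
#' @param method a `sers_method` or canonical code.
#' @param calibration list of calibration [spectrum()]s.
#' @param test list of test [spectrum()]s.
#' @param provenance character vector of free-text log lines.
#' @return an object of class `sers_dataset`.
#' @export
sers_dataset <- function(lab_id, method, calibration, test,
                         provenance = character()) {
  method <- parse_method_id(method, allowed = NULL)
  lab_id <- as.character(lab_id)
  for (s in c(calibration, test)) {
    if (!inherits(s, "sers_spectrum") || is.null(s$meta))
      stop_serscal("all dataset spectra must be sers_spectrum with metadata")
    if (s$meta$lab_id != lab_id || format(s$meta$method) != format(method))
      stop_serscal(sprintf(
        "spectrum metadata (%s, %s) inconsistent with dataset (%s, %s)",
        s$meta$lab_id, format(s$meta$method), lab_id, format(method)))
  }
  roles <- vapply(calibration, function(s) s$meta$role, "")
  if (length(roles) && any(roles != "calibration"))
    stop_serscal("calibration slot contains non-calibration spectra")
  conc <- vapply(calibration, function(s) s$meta$concentration, 0)
  if (length(unique(conc)) < 2L)
    stop_serscal("a dataset needs at least 2 distinct calibration concentration levels")
  structure(list(lab_id = lab_id, method = method,
                 calibration = calibration, test = test,
                 provenance = provenance),
            class = "sers_dataset")
}

#' @export
print.sers_dataset <- function(x, ...) {
  cat(sprintf("<SERS dataset %s / %s: %d calibration + %d test spectra>\n",
              x$lab_id, format(x$method), length(x$calibration),
              length(x$test)))
  invisible(x)
}

dataset_spectra <- function(ds) c(ds$calibration, ds$test)

log_provenance <- function(ds, msg) {
  ds$provenance <- c(ds$provenance, msg)
  ds
}

#' Load an interlaboratory collection from a manifest
#'
#' The manifest is a CSV (or data frame) with columns `file`, `lab`,
#' `method`, `role`, `level`, `replicate`, `concentration_uM`, one row per
#' spectrum file. Spectra are grouped into one dataset per (lab, method)
#' pair. Missing or extra replicates relative to the substrate's replicate
#' scheme (3 colloidal / 9 solid) are recorded in the dataset provenance,
#' not treated as errors; a manifest row pointing at a missing file is an
#' error.
#'
#' @param root directory against which relative `file` paths are resolved.
#' @param manifest data frame or path to the manifest CSV.
#' @return list of [sers_dataset()]s, ordered by (lab, method).
#' @export
load_ils_collection <- function(root, manifest) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("file", "lab", "method", "role", "level", "replicate",
            "concentration_uM")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop_serscal(paste("manifest lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(manifest$file)) {
    dup <- manifest$file[duplicated(manifest$file)][1L]
    stop_serscal(sprintf("conflicting manifest rows for file '%s'", dup))
  }
  # deterministic, order-independent grouping
  manifest <- manifest[order(manifest$lab, manifest$method, manifest$role,
                             manifest$level, manifest$replicate), ,
                       drop = FALSE]
  key <- paste(manifest$lab, manifest$method, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- manifest[key == k, , drop = FALSE]
    lab <- rows$lab[1L]; mcode <- rows$method[1L]
    specs <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      p <- rows$file[i]
      if (!file.exists(p)) p <- file.path(root, rows$file[i])
      if (!file.exists(p))
        stop_serscal(sprintf("manifest references missing file '%s'", rows$file[i]))
      meta <- spectrum_meta(lab, mcode, rows$role[i], rows$level[i],
                            rows$concentration_uM[i], rows$replicate[i])
      specs[[i]] <- read_spectrum_table(p, meta = meta)
    }
    is_cal <- rows$role == "calibration"
    ds <- sers_dataset(lab, mcode, specs[is_cal], specs[!is_cal])
    # replicate bookkeeping per (role, level)
    exp_rep <- expected_replicates(mcode)
    tab <- table(paste(rows$role, rows$level))
    for (lv in names(tab)) {
      n <- as.integer(tab[[lv]])
      if (n != exp_rep)
        ds <- log_provenance(ds, sprintf(
          "replicates for %s: %d present, %d expected (%+d)",
          lv, n, exp_rep, n - exp_rep))
    }
    ds <- log_provenance(ds, sprintf("loaded %d spectra from manifest",
                                     nrow(rows)))
    out[[k]] <- ds
  }
  out <- out[order(names(out))]
  names(out) <- NULL
  out
}

#' Screen a dataset for integrity problems
#'
#' Flags spectra that carry non-finite values, whose axis does not cover the
#' analyte band window, or that resemble a known contaminant (e.g. the
#' parafilm features that can dominate colloidal-sample spectra when focus
#' is wrong). Contaminant similarity is the Pearson correlation, on the
#' overlapping axis region, between the baseline-corrected and
#' area-normalized spectrum and each baseline-corrected, area-normalized
#' contaminant reference. The dataset verdict is `"reject"` when more than
#' half its spectra are contaminant-flagged.
#'
#' @param ds a [sers_dataset()].
#' @param contaminant_refs list of reference [spectrum()]s (may be empty).
#' @param corr_threshold correlation at or above which a spectrum is
#'   flagged (default 0.9).
#' @param band_window analyte window that every axis must cover, 1/cm.
#' @return an object of class `sers_integrity`: a list with `verdict`
#'   (`"pass"`/`"reject"`), a per-spectrum `flags` data frame, and counts.
#' @export
integrity_check <- function(ds, contaminant_refs = list(),
                            corr_threshold = 0.9,
                            band_window = c(715, 750)) {
  specs <- dataset_spectra(ds)
  n <- length(specs)
  flags <- data.frame(
    index = seq_len(n),
    role = vapply(specs, function(s) s$meta$role, ""),
    level = vapply(specs, function(s) s$meta$level_id, ""),
    replicate = vapply(specs, function(s) s$meta$replicate_id, 1L),
    non_finite = FALSE, window_not_covered = FALSE, contaminant = FALSE,
    max_contaminant_corr = NA_real_,
    stringsAsFactors = FALSE)
  refs <- lapply(contaminant_refs, contaminant_profile)
  for (i in seq_len(n)) {
    s <- specs[[i]]
    if (any(!is.finite(s$intensity)) || any(!is.finite(s$wavenumber))) {
      flags$non_finite[i] <- TRUE
      next
    }
    if (min(s$wavenumber) > band_window[1] || max(s$wavenumber) < band_window[2])
      flags$window_not_covered[i] <- TRUE
    if (length(refs)) {
      cors <- vapply(refs, function(r) contaminant_correlation(s, r), 0)
      flags$max_contaminant_corr[i] <- max(cors)
      if (max(cors) >= corr_threshold) flags$contaminant[i] <- TRUE
    }
  }
  verdict <- if (n > 0 && sum(flags$contaminant) > n / 2) "reject" else "pass"
  structure(list(verdict = verdict, flags = flags,
                 n_spectra = n,
                 n_flagged = sum(flags$non_finite | flags$window_not_covered |
                                   flags$contaminant),
                 corr_threshold = corr_threshold,
                 band_window = band_window),
            class = "sers_integrity")
}

#' @export
print.sers_integrity <- function(x, ...) {
  cat(sprintf("<integrity check: %s; %d/%d spectra flagged>\n",
              x$verdict, x$n_flagged, x$n_spectra))
  invisible(x)
}

# Baseline-correct and cache a contaminant reference for correlation.
contaminant_profile <- function(ref) {
  stopifnot(inherits(ref, "sers_spectrum"))
  corr <- baseline_correct(ref, method = "als")$corrected
  corr
}

# Pearson correlation between spectrum and contaminant reference on the
# overlap region, both baseline-corrected and normalized by integrated
# absolute area over the overlap.
contaminant_correlation <- function(s, ref) {
  lo <- max(min(s$wavenumber), min(ref$wavenumber))
  hi <- min(max(s$wavenumber), max(ref$wavenumber))
  if (hi <= lo) return(0)
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (sum(keep) < 8L) return(0)
  x <- s$wavenumber[keep]
  sc <- baseline_correct(spectrum(x, s$intensity[keep]), method = "als")$corrected
  ri <- stats::approx(ref$wavenumber, ref$intensity, xout = x)$y
  a1 <- trapz(x, abs(sc$intensity)); a2 <- trapz(x, abs(ri))
  if (a1 <= 0 || a2 <= 0) return(0)
  y1 <- sc$intensity / a1; y2 <- ri / a2
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0) return(0)
  stats::cor(y1, y2)
}
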