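#' Selection-workflow percentages
#'
#' Bookkeeping of the data-selection workflow of a collaborative trial:
#' how many datasets were planned, delivered, survived the integrity
#' screen, and survived the calibration-suitability gate. Percentages are
#' relative to the planned count and rounded half-up to one decimal, the
#' convention of collaborative-trial reporting (so 39/48 prints as 81.3%).
#'
#' @param planned number of datasets the study design called for.
#' @param delivered number actually received.
#' @param integrity_rejected number rejected by [integrity_check()].
#' @param calibration_rejected number rejected by the suitability gate.
#' @return an object of class `sers_selection`: counters plus derived
#'   percentages (`delivered_pct`, `post_integrity_pct`, `accepted_pct`).
#' @examples
#' selection_counters(48, 41, 2, 4)  # 85.4%, 81.3%, 72.9%
#' @export
selection_counters <- function(planned, delivered, integrity_rejected,
                               calibration_rejected) {
  post_integrity <- delivered - integrity_rejected
  accepted <- post_integrity - calibration_rejected
  if (any(c(planned, delivered, post_integrity, accepted) < 0) ||
      delivered > planned || post_integrity > delivered ||
      accepted > post_integrity)
    stop_serscal("selection counters must be non-increasing along the workflow")
  pct <- function(x) round_half_up(100 * x / planned, 1)
  structure(list(planned = planned, delivered = delivered,
                 post_integrity = post_integrity, accepted = accepted,
                 delivered_pct = pct(delivered),
                 post_integrity_pct = pct(post_integrity),
                 accepted_pct = pct(accepted)),
            class = "sers_selection")
}

#' @export
print.sers_selection <- function(x, ...) {
  cat("Data-selection workflow\n")
  cat(sprintf("  planned:          %d\n", x$planned))
  cat(sprintf("  delivered:        %d (%.1f%%)\n", x$delivered, x$delivered_pct))
  cat(sprintf("  after integrity:  %d (%.1f%%)\n", x$post_integrity,
              x$post_integrity_pct))
  cat(sprintf("  accepted:         %d (%.1f%%)\n", x$accepted, x$accepted_pct))
  invisible(x)
}

#' Quartile summary of pooled residuals
#'
#' Quartiles use the linear-interpolation convention between order
#' statistics (R's default quantile type 7). Residuals beyond the Tukey
#' fences `Q1 - 1.5 IQR` / `Q3 + 1.5 IQR` are flagged as outliers but are
#' never removed from figures of merit: flagging is diagnostic only.
#'
#' @param residuals numeric vector, `n >= 4`.
#' @return list with `q1`, `median`, `q3`, `iqr`, `fences` (lower, upper)
#'   and logical `flags`.
#' @export
quartile_summary <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 4L) stop_serscal("need at least 4 residuals for quartiles")
  q <- unname(stats::quantile(e, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[3] + 1.5 * iqr)
  list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr, fences = fences,
       flags = e < fences[1] | e > fences[2])
}

#' Rescale residuals by the test-set reference range
#'
#' Residual plots across methods calibrated over different analyte ranges
#' are made comparable by dividing each residual by the width of the test
#' set's reference-concentration range (distinct from the calibration-range
#' normalization used for the figures of merit).
#'
#' @param records prediction-record data frame (needs a `residual` column),
#'   or a bare numeric vector of residuals.
#' @param test_range `c(min, max)` of the test reference concentrations.
#' @return numeric vector of rescaled residuals (empty for empty input).
#' @export
residual_rescale <- function(records, test_range) {
  width <- test_range[2] - test_range[1]
  if (!is.finite(width) || width <= 0)
    stop_serscal("test reference range must have positive width")
  e <- if (is.data.frame(records)) records$residual else as.numeric(records)
  if (length(e) == 0L) return(numeric())
  e / width
}

#' Run the full interlaboratory analysis
#'
#' Applies the data-selection workflow to every dataset — integrity screen,
#' preprocessing, calibration with suitability gate, test-set prediction —
#' then pools prediction residuals per method across the accepted
#' laboratories and computes the figures of merit and residual summaries.
#' Deterministic given the collection and configuration.
#'
#' Method-level FoM normalization uses each dataset's calibration reference
#' range (residuals are normalized per record before pooling, and the bias
#' t-test runs on the normalized residuals, since one method may pool
#' laboratories calibrated over different ranges); the residual quartile
#' summaries instead rescale by the test-set reference range, the
#' convention for residual plots.
#'
#' @param collection list of [sers_dataset()]s.
#' @param preprocess a [preprocess_config()].
#' @param contaminant_refs list of contaminant reference spectra for
#'   [integrity_check()] (may be empty).
#' @param corr_threshold contaminant-correlation threshold.
#' @param band_window analyte integration window, 1/cm.
#' @param replicate_handling passed to [run_experiment()].
#' @param planned planned dataset count (defaults to `length(collection)`).
#' @param alpha significance level of the bias test.
#' @return an object of class `sers_ils`: `selection` (a
#'   [selection_counters()] object), `status` (per-dataset data frame),
#'   `records` (all prediction records), `methods` (per-method list with
#'   `fom`, quartile `summary`, rescaled residuals and `n_residuals`),
#'   and `models` (accepted calibration models).
#' @export
run_ils <- function(collection,
                    preprocess = preprocess_config(),
                    contaminant_refs = list(),
                    corr_threshold = 0.9,
                    band_window = c(715, 750),
                    replicate_handling = "mean",
                    planned = length(collection),
                    alpha = 0.01) {
  if (length(collection) == 0L) stop_serscal("empty collection")
  status <- data.frame(lab_id = character(), method_id = character(),
                       status = character(), reason = character(),
                       stringsAsFactors = FALSE)
  records <- list()
  models <- list()
  n_int_rej <- 0L; n_cal_rej <- 0L
  for (ds in collection) {
    key <- paste(ds$lab_id, format(ds$method))
    rep_int <- integrity_check(ds, contaminant_refs = contaminant_refs,
                               corr_threshold = corr_threshold,
                               band_window = band_window)
    if (rep_int$verdict == "reject") {
      n_int_rej <- n_int_rej + 1L
      status <- rbind(status, data.frame(
        lab_id = ds$lab_id, method_id = format(ds$method),
        status = "rejected-integrity",
        reason = sprintf("%d/%d spectra contaminant-flagged",
                         sum(rep_int$flags$contaminant), rep_int$n_spectra),
        stringsAsFactors = FALSE))
      next
    }
    ex <- tryCatch({
      pp <- run_preprocess(ds, preprocess)
      run_experiment(pp, band_window = band_window,
                     replicate_handling = replicate_handling)
    }, error = function(e) e)
    if (inherits(ex, "error")) {
      n_cal_rej <- n_cal_rej + 1L
      status <- rbind(status, data.frame(
        lab_id = ds$lab_id, method_id = format(ds$method),
        status = "rejected-calibration",
        reason = conditionMessage(ex), stringsAsFactors = FALSE))
      next
    }
    if (!ex$model$suitable) {
      n_cal_rej <- n_cal_rej + 1L
      status <- rbind(status, data.frame(
        lab_id = ds$lab_id, method_id = format(ds$method),
        status = "rejected-calibration", reason = ex$reason,
        stringsAsFactors = FALSE))
      next
    }
    status <- rbind(status, data.frame(
      lab_id = ds$lab_id, method_id = format(ds$method),
      status = "accepted", reason = "", stringsAsFactors = FALSE))
    r <- ex$records
    r$cal_width <- diff(ex$model$cal_range)
    records[[key]] <- r
    models[[key]] <- ex$model
  }
  all_records <- if (length(records)) do.call(rbind, records) else
    data.frame(lab_id = character(), method_id = character(),
               level_id = character(), reference = numeric(),
               predicted = numeric(), residual = numeric(),
               out_of_range = logical(), cal_width = numeric(),
               stringsAsFactors = FALSE)
  rownames(all_records) <- NULL
  selection <- selection_counters(planned, length(collection),
                                  n_int_rej, n_cal_rej)
  methods <- list()
  for (m in unique(all_records$method_id)) {
    rm <- all_records[all_records$method_id == m, , drop = FALSE]
    fom <- pooled_foms(rm$residual, rm$cal_width, alpha = alpha)
    test_range <- range(rm$reference)
    resc <- residual_rescale(rm, test_range)
    methods[[m]] <- list(method_id = m, n_residuals = nrow(rm), fom = fom,
                         test_range = test_range,
                         rescaled_residuals = resc,
                         summary = if (nrow(rm) >= 4L) quartile_summary(resc)
                         else NULL)
  }
  structure(list(selection = selection, status = status,
                 records = all_records, methods = methods, models = models,
                 band_window = band_window),
            class = "sers_ils")
}

#' Method-wise figures-of-merit table
#'
#' One row per method with the pooled residual count and the normalized
#' RMSEP, SEP and BIAS printed as whole percentages (half-up), the layout
#' used for method comparison in collaborative trials.
#'
#' @param x a [run_ils()] result.
#' @return data frame with columns `method`, `N`, `RMSEP`, `SEP`, `BIAS`
#'   (percent), `inv_SEP`, `quality_class`, `bias_significant`.
#' @export
fom_table <- function(x) {
  stopifnot(inherits(x, "sers_ils"))
  rows <- lapply(x$methods, function(m) {
    f <- m$fom
    data.frame(method = m$method_id, N = f$n,
               RMSEP = as.integer(round_half_up(100 * f$rmsep_norm)),
               SEP = as.integer(round_half_up(100 * f$sep_norm)),
               BIAS = as.integer(round_half_up(100 * f$bias_norm)),
               inv_SEP = round_half_up(f$inv_sep_norm, 2),
               quality_class = f$quality_class,
               bias_significant = f$bias_significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sers_ils <- function(x, ...) {
  cat("Interlaboratory SERS study analysis\n")
  print(x$selection)
  if (nrow(x$records)) {
    cat("\nFigures of merit by method (normalized, % of calibration range):\n")
    print(fom_table(x), row.names = FALSE)
  } else cat("\nno accepted datasets\n")
  invisible(x)
}

#' @export
summary.sers_ils <- function(object, ...) {
  structure(list(ils = object), class = "summary.sers_ils")
}

#' @export
print.summary.sers_ils <- function(x, ...) {
  print(x$ils)
  st <- x$ils$status
  rej <- st[st$status != "accepted", , drop = FALSE]
  if (nrow(rej)) {
    cat("\nRejected datasets:\n")
    print(rej, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.sers_ils <- function(x, which = c("predicted", "residuals"), ...) {
  which <- match.arg(which)
  r <- x$records
  if (!nrow(r)) stop_serscal("nothing to plot: no accepted datasets")
  if (which == "predicted") {
    graphics::plot(r$reference, r$predicted, col = factor(r$method_id),
                   xlab = "reference concentration (uM)",
                   ylab = "predicted concentration (uM)",
                   main = "Predicted vs reference", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    resc <- unlist(lapply(x$methods, `[[`, "rescaled_residuals"))
    grp <- factor(rep(names(x$methods),
                      vapply(x$methods, function(m) length(m$rescaled_residuals), 0L)))
    graphics::boxplot(resc ~ grp, xlab = "method",
                      ylab = "residual / test range",
                      main = "Rescaled residuals by method", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Write the report bundle of an interlaboratory run
#'
#' Writes, under `outdir`: `fom_by_method.csv` (the [fom_table()]),
#' `predictions.csv` (all prediction records), `selection_log.csv`
#' (per-dataset status), `manifest.json` (selection counters, configuration
#' echo, package version, and the seed when given), and figures
#' (`predicted_vs_reference.png`, `residuals_by_method.png`,
#' `residual_distributions.png`) when any dataset was accepted. CSV output
#' is deterministic: rerunning on the same inputs reproduces the files
#' byte for byte.
#'
#' @param x a [run_ils()] result.
#' @param outdir output directory (created if needed).
#' @param seed optional seed to record in the manifest.
#' @param config optional configuration object echoed into the manifest.
#' @return character vector of written paths, invisibly.
#' @export
make_report <- function(x, outdir, seed = NULL, config = NULL) {
  stopifnot(inherits(x, "sers_ils"))
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop_serscal(sprintf("cannot create '%s'", outdir))
  paths <- character()
  w <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(fom_table(x), "fom_by_method.csv")
  w(x$records, "predictions.csv")
  w(x$status, "selection_log.csv")
  manifest <- list(
    selection = unclass(x$selection),
    band_window = x$band_window,
    package_version = as.character(utils::packageVersion("serscal")),
    seed = seed,
    config = if (!is.null(config)) unclass(config) else NULL)
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, mp)
  if (nrow(x$records)) {
    fig <- function(name, expr) {
      p <- file.path(outdir, name)
      grDevices::png(p, width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr()
      paths <<- c(paths, p)
    }
    fig("predicted_vs_reference.png", function() plot(x, "predicted"))
    fig("residuals_by_method.png", function() {
      plot(x, "residuals")
      for (m in x$methods) {
        if (!is.null(m$summary)) {
          graphics::abline(h = m$summary$fences, lty = 3, col = "grey40")
        }
      }
    })
    fig("residual_distributions.png", function() {
      resc <- unlist(lapply(x$methods, `[[`, "rescaled_residuals"))
      graphics::hist(resc, breaks = 30,
                     xlab = "residual / test range", main = "Pooled rescaled residuals")
    })
  }
  invisible(paths)
}
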