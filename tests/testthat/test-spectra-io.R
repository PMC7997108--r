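test_that("spectrum tables parse across delimiters and survive re-sorting", {
  d <- withr::local_tempdir()
  rows <- list(comma = "700,1.0\n710,2.0\n720,1.5",
               tab = "700\t1.0\n710\t2.0\n720\t1.5",
               semicolon = "700;1.0;extra\n710;2.0;x\n720;1.5;y",
               whitespace = "700  1.0\n710  2.0\n720  1.5")
  for (nm in names(rows)) {
    p <- file.path(d, paste0(nm, ".txt"))
    writeLines(c("# comment line", rows[[nm]]), p)
    s <- read_spectrum_table(p)
    expect_equal(s$wavenumber, c(700, 710, 720), info = nm)
    expect_equal(s$intensity, c(1.0, 2.0, 1.5), info = nm)
  }
  # descending storage yields the identical ascending spectrum
  p <- file.path(d, "desc.txt")
  writeLines(c("720,1.5", "710,2.0", "700,1.0"), p)
  expect_equal(read_spectrum_table(p),
               read_spectrum_table(file.path(d, "comma.txt")))
})

test_that("malformed spectrum tables raise the documented errors", {
  d <- withr::local_tempdir()
  w <- function(lines) {
    p <- tempfile(tmpdir = d, fileext = ".csv")
    writeLines(lines, p)
    p
  }
  expect_error(read_spectrum_table(file.path(d, "absent.csv")), "cannot read")
  expect_error(read_spectrum_table(w("700,1.0")), "fewer than 2")
  expect_error(read_spectrum_table(w(c("700,1.0", "710,NaN", "720,2"))),
               "non-finite value at row 2")
  expect_error(read_spectrum_table(w(c("700,1.0", "700,2.0", "720,2"))),
               "duplicated wavenumbers")
})

test_that("write/read round-trip preserves values at full precision", {
  d <- withr::local_tempdir()
  set.seed(3)
  s <- spectrum(sort(runif(50, 400, 1800)), rnorm(50) * exp(rnorm(50, 0, 5)))
  p <- file.path(d, "rt.csv")
  write_spectrum_table(s, p)
  s2 <- read_spectrum_table(p)
  expect_identical(s2$wavenumber, s$wavenumber)
  expect_identical(s2$intensity, s$intensity)
})

test_that("spectrum and metadata constructors enforce their invariants", {
  expect_error(spectrum(1:3, 1:2), "equal length")
  expect_error(spectrum(700, 1), "at least 2")
  expect_error(spectrum(c(700, 710), c(1, NA)), "non-finite value at row 2")
  expect_error(spectrum_meta("P01", "cAg@785", "calibration", "C0", NA), "known concentration")
  expect_error(spectrum_meta("P01", "cAg@785", "test", "X1", -3), ">= 0")
  expect_error(spectrum_meta("P01", "cAg@785", "test", "X1", 5, 0), "replicate_id")
  expect_error(parse_method_id("qAg@785"), "malformed")
  expect_error(method_id("colloidal", "Au", 532), "not in the accepted set")
  m <- method_id("colloidal", "Au", 532, allowed = NULL)
  expect_equal(format(m), "cAu@532")
  expect_equal(expected_replicates("sAg@785"), 9L)
  expect_equal(expected_replicates("cAg@785"), 3L)
})

test_that("a manifest loads into datasets with replicate bookkeeping", {
  d <- withr::local_tempdir()
  gcoll <- generate_collection(tiny_config())
  manifest <- write_ils_collection(gcoll$datasets, d, truth = gcoll$truth)
  # 2 labs x 1 method x (5 cal + 5 test) x 3 reps
  expect_equal(nrow(manifest), 2 * 10 * 3)
  loaded <- load_ils_collection(d, file.path(d, "manifest.csv"))
  expect_length(loaded, 2)
  expect_equal(length(loaded[[1]]$calibration) + length(loaded[[1]]$test), 30)
  # loading is order-independent
  shuffled <- manifest[sample.int(nrow(manifest)), ]
  loaded2 <- load_ils_collection(d, shuffled)
  expect_equal(loaded2, loaded)
  # spectra round-trip exactly
  orig <- gcoll$datasets[[1]]$calibration[[1]]
  got <- loaded[[1]]$calibration[[1]]
  expect_equal(got$intensity, orig$intensity)
  expect_equal(got$meta$concentration, orig$meta$concentration)
})

test_that("manifest problems are reported as specified", {
  d <- withr::local_tempdir()
  gcoll <- generate_collection(tiny_config(labs_per_method = 1L))
  manifest <- write_ils_collection(gcoll$datasets, d)
  # a missing replicate is noted in provenance, not fatal
  drop_one <- manifest[-1, ]
  loaded <- load_ils_collection(d, drop_one)
  expect_length(loaded, 1)
  expect_true(any(grepl("2 present, 3 expected", loaded[[1]]$provenance)))
  # a row pointing at a missing file is fatal
  bad <- manifest
  bad$file[1] <- "no_such_file.csv"
  expect_error(load_ils_collection(d, bad), "missing file")
  # two rows for one file conflict
  dup <- rbind(manifest, manifest[1, ])
  expect_error(load_ils_collection(d, dup), "conflicting")
})

test_that("integrity screen flags contamination and window coverage", {
  cfg <- tiny_config(labs_per_method = 1L)
  gcoll <- generate_collection(cfg)
  ds <- gcoll$datasets[[1]]
  ref <- contaminant_reference(cfg)

  # clean dataset passes with zero contaminant flags
  rep0 <- integrity_check(ds, contaminant_refs = list(ref))
  expect_equal(rep0$verdict, "pass")
  expect_equal(sum(rep0$flags$contaminant), 0)

  # spectra that are pure contaminant plus 1% noise correlate > 0.9 and
  # push the dataset over the >50% rejection rule
  set.seed(99)
  noisy_contam <- function(s) {
    sigma <- 0.01 * max(ref$intensity)
    spectrum(ref$wavenumber, ref$intensity + rnorm(length(ref$wavenumber), 0, sigma),
             meta = s$meta)
  }
  bad <- ds
  bad$calibration <- lapply(bad$calibration, noisy_contam)
  bad$test <- lapply(bad$test, noisy_contam)
  rep1 <- integrity_check(bad, contaminant_refs = list(ref), corr_threshold = 0.9)
  expect_equal(rep1$verdict, "reject")
  expect_true(all(rep1$flags$max_contaminant_corr > 0.9))

  # one spectrum with an axis missing the analyte window is flagged alone
  part <- ds
  s <- part$calibration[[1]]
  keep <- s$wavenumber >= 800
  part$calibration[[1]] <- spectrum(s$wavenumber[keep], s$intensity[keep],
                                    meta = s$meta)
  rep2 <- integrity_check(part)
  expect_equal(rep2$verdict, "pass")
  expect_equal(sum(rep2$flags$window_not_covered), 1)

  # non-finite data are caught even if injected after construction
  nf <- ds
  nf$calibration[[2]]$intensity[10] <- NA_real_
  rep3 <- integrity_check(nf)
  expect_equal(sum(rep3$flags$non_finite), 1)
})
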