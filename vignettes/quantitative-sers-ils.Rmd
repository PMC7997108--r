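---
title: "Assessing quantitative SERS methods across laboratories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing quantitative SERS methods across laboratories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serscal)
```

## The problem

A quantitative SERS method couples a plasmonic substrate (colloidal or solid,
Ag or Au) with a laser wavelength and a fixed operating procedure. Its
fitness for routine use is not a single-laboratory property: the question a
collaborative trial answers is how closely *different* laboratories, with
different instruments and operators, agree when they quantify the same
analyte with the same method. `serscal` implements the analysis side of such
a trial for the canonical test system — adenine in buffer, quantified
through its ring-breathing band at 715–750 cm⁻¹ — together with a synthetic
data generator that reproduces the statistical structure the analysis
assumes, so every stage can be validated against known ground truth.

The analysis unit is a *dataset*: all spectra from one laboratory with one
method, split into a calibration set (known concentrations, levels C0, C1,
…) and a test set (blind levels X1–X5). Replicates follow the substrate
scheme: 3 per sample for colloids (one per colloid batch), 9 for solid
substrates (3 spots × 3 substrates).

## The pipeline

Each dataset passes, in order, through:

1. **Integrity screen** (`integrity_check()`). Flags non-finite traces, axes
   that do not cover the analyte window, and spectra that correlate (Pearson
   r ≥ 0.9 after baseline correction and area normalization on the
   overlapping axis region) with a user-supplied contaminant reference —
   a mechanical surrogate for the expert inspection that, in real trials,
   catches artifacts such as parafilm bands from incorrectly focused
   colloidal samples. A dataset is rejected outright when more than half its
   spectra are contaminant-flagged; the threshold and the references are
   explicit arguments because no fixed rule can substitute for inspection in
   general.
2. **Savitzky–Golay smoothing** (window 9 points, order 2 by default).
3. **Resampling** to a 1 cm⁻¹ grid on the intersection of all axes, and
   **range selection** to 400–1800 cm⁻¹.
4. **Baseline correction** (below).
5. **EMSC normalization** against a per-dataset reference: the pointwise
   median of the dataset's own calibration spectra, scaled to unit mean
   absolute intensity over the EMSC fit region. Per-dataset references keep
   laboratories statistically independent; the scaling makes corrected
   spectra gain-free, so spectra of equal concentration from different
   laboratories become superimposable.

The quantitative response is the trapezoidal band area over 715–750 cm⁻¹,
averaged over a sample's replicates (per-replicate fitting is available as
`replicate_handling = "individual"`; with balanced designs both see the
same level means). Concentration is regressed on area — *inverse*
calibration — so unknowns are predicted directly from the fitted line.
Predictions are never clipped: negative or out-of-range values are flagged
but reported as-is, because truncation would silently bias the pooled
residuals the figures of merit are built from.

### Suitability gating

A calibration predicts only if r² ≥ 0.6 **and** the overall-regression
F-test p ≤ 0.01 (both thresholds exact; reason codes report which gate
failed). With few calibration points the F gate is the binding one — at
n = 5, r² = 0.6 corresponds to p ≈ 0.12 — which is the statistically sound
behaviour: a barely-correlated 5-point line should not predict. The
F statistic is the overall-regression one (the lack-of-fit variant would
need replicate-level responses, which the default replicate averaging
removes).

### Figures of merit

Pooled per method across accepted laboratories, the residuals
eᵢ = ĉᵢ − cᵢ give

$$\mathrm{BIAS} = \tfrac1N\sum e_i,\qquad
  \mathrm{RMSEP} = \sqrt{\tfrac1N\sum e_i^2},\qquad
  \mathrm{SEP} = \sqrt{\tfrac1{N-1}\sum (e_i-\mathrm{BIAS})^2}.$$

With these denominators RMSEP² = BIAS² + SEP²·(N−1)/N holds *exactly*
(`iso_identity_check()` verifies it to 1e−12), and the familiar
RMSEP² ≈ SEP² + BIAS² follows for large N. The denominator convention
matters: published method tables can legitimately show SEP > RMSEP (e.g.
SEP 29% against RMSEP 28% at N = 25), which is arithmetically impossible if
both used N — `reference_method_foms()` ships such a table and the test
suite uses it as a regression check. Outlying residuals are flagged by
Tukey fences (quartiles by linear interpolation, R type 7) but **never
removed** from the figures of merit; removal would only flatter the data.

Because one method may pool laboratories calibrated over different
concentration ranges, each record's residual is normalized by its own
dataset's calibration range before pooling; the normalized slots of the
result (and the bias t test, which runs on normalized residuals) come from
that pooled vector, while raw slots summarize the raw residuals. Residual
*plots* instead rescale by the test-set reference range — the two ranges are
carried separately because they serve different comparisons. The bias t test
is the two-sided one-sample Student test at the 99% confidence level; the
degenerate zero-variance case is resolved explicitly (nonzero mean → t = ∞,
significant). 1/SEP (normalized) grades each method: >4 screening, >10
quality control, >15 quantification, strict inequalities.

## The synthetic generator

`generate_collection()` draws whole collections from

$$I(\nu) = \mathrm{baseline}(\nu)
  + g_{\mathrm{lab}}\,[A(c)\,(1+\delta_{\mathrm{rep}})\,\phi(\nu)
  + M(\nu)] + \varepsilon(\nu),$$

with $A(c) = \alpha\,cK/(K+c)$ (linear when $K=\infty$), $\phi$ a unit-area
50/50 pseudo-Voigt at 733 cm⁻¹ (FWHM 14 cm⁻¹), $g_{\mathrm{lab}}\sim
N(1,0.15)$, $\delta_{\mathrm{rep}}\sim N(0,0.2)$ applied to the analyte band
only (per-spot enhancement fluctuation, the dominant SERS error source),
and pointwise noise SD $\sigma_a + \sigma_p A(c)$, whose proportional part
reproduces the spread-grows-with-concentration pattern real trials show.
Defaults chosen once and documented here: 6 methods × 8 labs; nine
calibration levels log-spaced over 1–100 µM (C0–C8); five test levels
interleaved inside that range (whether real trials reuse calibration levels
is unknowable from outside, so both layouts are supported); a gentle
quadratic fluorescence baseline; additive noise 1 count, proportional
0.5% of $A(c)$. With 3–9 replicates averaged these defaults land in the
few-percent normalized-SEP regime of a well-behaved method.

Two design points deserve emphasis:

* **Fixed matrix bands.** $M(\nu)$ (bands at 960, 1095, 1450 cm⁻¹) models
  the concentration-invariant buffer/substrate background every real SERS
  spectrum carries. It is not decoration: EMSC estimates its gain from
  spectral content that does *not* scale with the analyte. A synthetic
  spectrum whose only feature is the analyte band would make the EMSC gain
  absorb the concentration signal itself, collapsing every corrected
  spectrum onto the reference and the calibration design with it.
* **Truncated band profiles.** Profiles are evaluated within ±5 FWHM and
  renormalized to unit area. Pure Lorentzian tails decay only as 1/Δν², so
  without truncation a trace of analyte signal reaches every spectral
  region and no fit-region mask can fully isolate the gain estimate; the
  truncation confines each band to its neighbourhood, which is also how
  measured bands behave relative to noise.

A `TruthRecord` (per-lab gains, per-spectrum true band areas, true test
concentrations, config echo) accompanies every collection, and generation
is bit-reproducible from the seed. Contamination (probability per dataset)
adds parafilm-like bands at 733 and 1440 cm⁻¹ — one inside, one outside the
analyte window — to exercise the integrity screen.

What the generator does **not** emulate: electromagnetic/chemical
enhancement physics, photodegradation, wavenumber miscalibration, drift
between calibration and test acquisition, or non-Gaussian outliers. Passing
tests therefore certify the *analysis*, not the chemistry: they show the
pipeline recovers what the model injects, at the study's scale and noise
structure, and say nothing about substrate batches or instruments beyond
the gain/fluctuation model above.

## Numerical design choices

**Baseline.** Three methods are provided. Whittaker-ALS (`"als"`,
λ = 1e5, p = 0.01) and iterative polynomial clipping (`"modpoly"`) are the
textbook choices and remain available per spectrum. The pipeline default is
`"aspoly"`: the same asymmetric reweighting as ALS but fitting a polynomial
(degree 4), with the weight pattern converged once on the pointwise median
of the dataset's calibration spectra and then applied to every spectrum
(`baseline_shared = TRUE`). Two properties motivated this. First, sharing
the pattern makes the baseline stage one *fixed linear operator* per
dataset, so all spectra are treated identically and no
concentration-dependent baseline distortion enters — with per-spectrum
weight patterns the distortion reaches percent level and, among other
things, breaks the exact noise-free recovery the test suite demands.
Second, a polynomial baseline's imprint on the spectrum is itself exactly a
polynomial, which the EMSC background term absorbs completely as long as
the EMSC degree (default 4) is at least the baseline degree — whereas the
Whittaker smoother leaks a slowly decaying, non-polynomial trace of each
band into the EMSC fit region. These parameters stand in for the
unpublished protocol values of real trials and are all exposed in
`preprocess_config()`.

**EMSC fit mask.** The gain is estimated with the analyte band ±65 cm⁻¹
excluded from the fit (the correction is applied everywhere). Without the
mask the analyte's own signal biases the gain; the guard width covers the
truncated band support plus smoothing spill-over. `emsc()` reports the
background coefficients re-expanded in raw wavenumber (fitted internally on
a centered, scaled axis for conditioning), and refuses spectra whose
projection on the reference is numerically zero.

**Degenerate inputs and tie-breaks.** Duplicate wavenumbers, descending
axes, empty crops, windows off the grid, all-equal calibration areas,
zero-width normalization ranges and zero-variance residual vectors all have
defined behaviour (error or documented special case) and tests. Report
percentages round half-up (one decimal for selection percentages, whole
percent for FoM tables) — base R's round-half-even would turn 81.25% into
81.2% where trial reports print 81.3%.

**Problem sizes.** The test suite validates noise-free recovery at the full
study scale (48 datasets, ~4000 spectra, < 1e−6 relative error — measured
~4e−16) and uses 2-lab single-method collections for the faster unit
tests; Monte-Carlo checks use 200–1000 replicates. These sizes are the
package's own verification choices and run in well under a minute each.

## Limitations

The pipeline deliberately mirrors a specific trial design: univariate
band-area response, straight-line inverse calibration (nonlinear models are
out of scope even though saturating synthetic data can be generated),
unweighted OLS despite heteroscedastic spread at high concentration, no
limit-of-detection estimation, no internal-standard normalization, and
pooled-residual figures of merit rather than the ISO 5725-2 ANOVA split
into repeatability and between-laboratory variance components. The
integrity screen needs user-supplied contaminant references; it cannot
discover unknown artifacts. Vendor binary formats are not read — spectra
enter as two-column text tables plus a manifest.
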