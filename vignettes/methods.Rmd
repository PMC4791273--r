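---
title: "Methods: ploidy typing, IMS preprocessing, supervised segmentation, and survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy typing, IMS preprocessing, supervised segmentation, and survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsmarker)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the test suite can show. The package links
three stages that in the original workflow were carried out by separate
instruments and proprietary software: DNA image cytometry, MALDI imaging
mass spectrometry (IMS) with supervised classification, and
tissue-microarray (TMA) survival statistics.

## 1. Auer typing of DNA-content histograms

Each nucleus contributes one DNA-content value in c-units, anchored so the
lymphocyte staining controls equal 2c (`to_c_values()`: c = 2·IOD/control
mean). The histogram-type rules are:

* **Type I** — a single stem line in the diploid region [1.5, 2.5]c and
  fewer than 10% of nuclei above 2.5c.
* **Type II** — stem lines in the tetraploid region [3.5, 4.5]c (alone or
  with a diploid line) jointly holding more than 90% of nuclei.
* **Type III** — a proliferating near-diploid population with nuclei spread
  between the diploid and tetraploid regions and under 5% above 4.5c.
* **Type IV** — more than 5% of nuclei, and/or distinctly scattered values,
  above 4.5c. Types I–III are euploid; IV is aneuploid.

As written, the rules overlap, so `classify_auer()` applies them with fixed
precedence **IV → II → I → III**: aneuploidy (the >4.5c criterion) is
decided first, then the two specific euploid shapes, with type III as the
fallback for euploid populations failing I and II. This makes the "< x%"
side-conditions mutually consistent and every non-empty histogram
classifiable exactly once — a property the test suite checks over randomly
generated histograms.

Design notes:

* Region boundaries are closed ([1.5, 2.5], [3.5, 4.5]); "exceeding" is
  strict (> 2.5c, > 4.5c), matching the inequality notation of the rules.
* The "distinctly scattered" clause is subjective, so it is implemented as
  an optional second trigger (off by default): at least 20 nuclei above 5c
  with a histogram coefficient of variation above 0.25. The quantitative
  >5% rule is the reproducible core. One published sample (stem line 2.03,
  0.8% of 3,621 nuclei above 5c) is labelled aneuploid although the >5%
  rule fails — presumably via this clause — and is therefore not used as a
  test case. Because the threshold on "5c-exceeding" counting is likewise
  unstated, the result reports both the >4.5c and the >5c counts.
* Stem lines (`detect_stem_lines()`) are local maxima of a 0.2c-wide
  binned histogram holding at least 5% of nuclei; adjacent qualifying bins
  merge, and the line is reported as the mean c-value in the mode's bin
  neighbourhood, to 2 decimals — the precision of published ploidy tables.
  A 10× finer exhaustive binning serves as the independent oracle in tests.
* Fewer than 500 nuclei raises a quality flag rather than an error: the
  500-nuclei criterion is an acquisition guideline, not a property of the
  classification rules.

## 2. Spectral preprocessing

The chain runs in a fixed, logged order:
restrict → exclude null spectra → recalibrate → TIC-normalize →
convex-hull baseline (`preprocess_ims()`). Normalization deliberately
precedes baseline correction, following the order the source workflow
states; each step writes one log line with its parameters.

* **Mass range** [2,000, 25,000] Da — the linear-TOF observation range.
* **Null spectra** are those with TIC ≤ 10⁻⁶ × the slide's median TIC;
  they are excluded with a machine-readable reason, and retained + excluded
  always equals the input pixel count.
* **Recalibration** estimates one multiplicative m/z factor per spectrum
  (a global ppm shift) from the median ratio of its top-10 matched local
  maxima to the slide-average reference — the simplest model consistent
  with a ppm-expressed cap. Estimated |shift| > 1,000 ppm excludes the
  spectrum ("shift over limit"). Aligned spectra are resampled onto the
  reference axis by linear interpolation.
* **TIC normalization** scales intensities to unit sum (checked to
  1 ± 1e−12 in tests).
* **Convex-hull baseline**: the baseline is the lower convex hull of the
  spectrum's points (Andrew's monotone chain), linearly interpolated
  between hull vertices. The *flatness* knob (default 0.8) controls a
  pre-hull running-median smoothing with window (1 − flatness) × n points;
  the hull is anchored on the pointwise minimum of the raw and smoothed
  traces. Anchoring on the minimum guarantees the baseline never exceeds
  the raw signal, so the corrected spectrum is non-negative everywhere and
  re-application changes nothing (exact idempotence; tested at 1e−9). The
  original software's "baseline flatness 0.8" parameter has undocumented
  semantics; this smoothing is the declared interpretation, keeping hull
  subtraction as the defined core.
* **Peak picking** on class-average spectra: local maxima with apex above
  3 × noise, noise being the median absolute deviation (×1.4826) of the
  corrected average — a robust, standard estimate standing in for an
  unpublished proprietary criterion. The apex must also rise that far
  above its flanking minima (prominence), which suppresses noise ripples
  riding the broad concave residuals a convex hull cannot remove. Window
  bounds are the flanking local minima; when the descending runs of two
  peaks share a flat valley, the boundary is placed at the deepest point
  between the apexes so windows never overlap.
* **End-point integration**: trapezoidal area above the chord joining the
  window's endpoint intensities, clamped at 0. This makes the area
  invariant to adding any affine function of m/z across the window
  (tested), and matches a closed-form triangle exactly and a fine-grid
  numeric oracle within 0.5%.

## 3. Discovery and pixel classification

Regions of interest (ROIs) label the training spectra. Per-peak
discrimination uses the rank-based ROC AUC (concordant pairs + half the
ties over all pairs), with the positive class defaulting to the
higher-mean class and never flipped to max(AUC, 1 − AUC); peaks with
AUC > 0.75 (strict) are selected. The AUC implementation is checked against
brute-force pair enumeration on every input up to 30 values.

Two classifier kinds are provided:

* **Supervised neural network (SNN)** — the proprietary original is
  undescribed, so the smallest architecture honouring "neural network"
  with reproducible training is used: one hidden layer of 2 × n_peaks
  logistic units, softmax output, full-batch BFGS training (via `nnet`)
  on standardized peak areas, seeded initialization, weight decay 1e−4.
* **Quick classifier** — weighted nearest-centroid, per-peak weights
  proportional to the between/within class variance ratio, normalized to
  sum 1 (analogous to the printed per-peak "weight" columns of the
  published models). Zero within-class variance is treated as a perfectly
  reliable feature, not a useless one, so noise-free data remain
  classifiable.

Model selection maximizes **recognition capability**: stratified 5-fold
cross-validated per-class correct-classification percentage, averaged;
exact ties prefer the SNN. Whole-slide classification assigns each pixel
the argmax class, with confidence = top-class posterior; confidence below
the threshold (default 0.5 — the original's rejection rule is unpublished)
or upstream exclusion leaves the pixel UNCLASSIFIED, so every grid pixel
appears exactly once in the map. Annotation returns all proteins of the
lookup table within ±1 Da of a query peak, sorted by mass difference. For
multi-protein table rows the source prints only a mass *range*, so the
fixture stores interval bounds and the difference is the distance to the
nearest bound; no per-protein masses were invented.

The genetic-algorithm classifier of the original software is deliberately
out of scope (its final models were SNN-based), as is any attempt to
reproduce the published classification percentages: the raw imaging data
were never deposited.

## 4. Clinical statistics

On the bundled 28-record TMA cohort (10 normal mucosa, 9 diploid, 9
aneuploid carcinomas):

* **Medians** are rounded half-up to 4 decimals (clinical-table
  convention; R's `round()` is round-half-even, hence `round_half_up()`).
* **Mann–Whitney U** uses midranks; the p-value is exact for tie-free
  total n ≤ 12 and otherwise a normal approximation with tie and
  continuity correction (via `wilcox.test`).
* **Optimal cutoff**: candidates are the midpoints between adjacent
  distinct values plus the two boundary cutoffs; the winner maximizes
  Youden's index (sensitivity + specificity − 1), ties breaking toward
  higher specificity. A case is marker-positive iff value > cutoff
  (strict); equality is assigned negative and flagged, since the published
  rule's two strict inequalities leave equality undefined. The cutoff is
  reported rounded half-up to 4 decimals and sensitivity/specificity to
  whole percent — conventions that regenerate the printed 0.4489 (midpoint
  of 0.4448 and 0.4529), 44% (4/9) and 89% (8/9) exactly.
* **Survival**: Kaplan–Meier product-limit curves, the log-rank test, and
  a univariate Cox model (`survival::coxph`, Newton–Raphson to 1e−10).
  Ties default to **Breslow**, the typical clinical-software default of
  the study's era, with Efron available; with the fixture, Breslow and the
  observed-information Wald interval exp(β̂ ± z₀.₉₇₅·SE) reproduce the
  published HR and both CI bounds to all printed digits, so no further tie
  variants were explored. Monotone-likelihood fits (huge SE) are flagged
  non-convergent rather than silently reported.
* **Binary regression** of marker status on ploidy: logistic fit with the
  Wald p, Fisher's exact p alongside; a zero cell triggers Haldane (+0.5)
  continuity handling for the odds ratio, flagged.

One published summary — 89% sensitivity at 100% specificity for the
normal-vs-carcinoma IP comparison — does not recompute from the printed
duplicate-averaged IP values (they give 15/18 = 83% at 100% specificity),
possibly reflecting pre-averaging data; it is documented here as a known
discrepancy and asserted nowhere.

## 5. What the synthetic generators emulate — and what they do not

`generate_ims_slide()` produces one profile spectrum per grid pixel on a
shared axis: Gaussian peaks (linear-TOF peaks are broad and smooth) whose
FWHM scales with m/z (constant resolving power, default 800); class-mean
apex intensities with relative noise `cv` (default 0.2, two-fold
between-class contrast at the six published marker masses); a smooth
positive baseline (decaying exponential + slow sinusoid + floor, default
amplitude 20) chosen to give the hull corrector nontrivial curvature,
including concave stretches it provably cannot remove; per-pixel
multiplicative calibration jitter (default 200 ppm s.d.); additive
Gaussian noise clamped at zero; and a planted fraction of near-zero
("null") pixels to exercise the exclusion path. Pixel pitch defaults to
90 µm. All randomness flows through one seeded generator per call that
restores the session RNG state, so identical spec + seed is bit-identical.

Not emulated: isotope envelopes, adducts, matrix cluster ions, detector
saturation, spatial intensity gradients, and chimeric boundary pixels.
Passing tests therefore demonstrate that the chain is correct *given its
assumptions*, not that real tissue would classify at the published rates.

`generate_dna_histogram()` draws nuclei from Gaussian stem lines, a
scattered >4.5c component (uniform on [4.6, 9.5]), and a proliferating
remainder spread between the regions (uniform on [2.55, 3.45]); it also
returns the Auer type implied analytically by the spec (normal-CDF region
masses), which the classifier must recover. Recovery is tested at ≥95%
over 24 seeds per type on non-borderline specs (stem lines at least three
within-line standard deviations from region boundaries).

`generate_cohort()` draws exponential survival with a multiplicative
hazard for marker-positive patients (default HR 13, baseline hazard
0.005/month, administrative censoring at 174 months — the follow-up
interval of the clinical comparison) and logit-normal immunopositivity per
group. Cox recovery is tested at 200 patients/arm: point estimate within
30% and ≥90% CI coverage over 100 seeded cohorts.

## Problem sizes and runtime

Test slides use a 2,000–10,000 Da range at 4 Da sampling on 10×6 to 16×10
grids (60–160 spectra), sizes at which the full discovery chain —
preprocessing, picking, ROC filtering, training both model kinds with
cross-validation, and whole-slide mapping — completes in seconds while
exercising every code path; histograms use ~1,000 nuclei, matching
published per-sample cell counts. The whole suite runs in well under a
minute.

## Known limitations

* The imzML binary format is not read or written; slides interchange as
  long-format TSV (`write_ims_tsv()`/`read_ims_tsv()`), masks and maps as
  TSV (PNG maps optionally via the `png` package).
* Only the univariate Cox model is implemented (the validated claim);
  no multivariable adjustment, no imputation.
* The SNN and quick classifiers are declared stand-ins for proprietary,
  unpublished algorithms; their published per-peak "weight" columns are
  shipped as fixture data and never reproduced.
* Interfaces are R functions plus `run_pipeline()`; there is no shell
  entry point.
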