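# imsmarker

Ploidy-associated biomarker discovery from MALDI imaging mass spectrometry
(IMS), with clinical survival validation — an open, tested re-implementation
of a three-stage colorectal-cancer analysis chain:

1. **DNA image cytometry (ploidy)** — per-nucleus DNA-content histograms in
   c-units (2c = normal diploid content, anchored by lymphocyte controls)
   are classified into Auer types I–IV; types I–III are euploid, type IV
   (> 5% of nuclei beyond the tetraploid region, i.e. > 4.5c) is aneuploid.
2. **IMS biomarker discovery** — linear-TOF profile spectra (m/z
   2,000–25,000, 90 µm pixels) are preprocessed (mass-range restriction,
   recalibration by spectral alignment with a 1,000 ppm shift cap and
   exclusion of null spectra, total-ion-count normalization, convex-hull
   baseline correction), peak-picked on class-average spectra, integrated
   with end-point (chord-subtracted) areas, filtered by ROC AUC > 0.75, and
   classified per pixel by a supervised neural network or a weighted
   nearest-centroid "quick" classifier with an UNCLASSIFIED rejection
   state. Peaks are annotated against a protein-mass table at ± 1 Da.
3. **Clinical validation** — on the bundled 28-patient tissue-microarray
   cohort (10 normal mucosa, 9 diploid and 9 aneuploid carcinomas with
   thymosin β-4 immunopositivity, IP): group medians, Mann–Whitney U,
   Youden-optimal dichotomization (positive iff IP > cutoff), Kaplan–Meier
   and log-rank, a univariate Cox proportional-hazards model
   (HR = exp(β̂), 95% Wald CI from the observed information, Breslow
   ties), and the ploidy–marker binary regression.

The raw imaging data behind the original study were never deposited, so the
spectral stages are exercised on synthetic slides whose statistical
structure (planted marker peaks at m/z 2,395, 3,376, 4,761, 4,977, 6,663
and 8,581; smooth positive baselines; ppm-scale calibration jitter; null
pixels) matches what the pipeline assumes; the clinical stage reproduces
the published statistics exactly from the in-package cohort fixture.

## Worked example

```r
library(imsmarker)

cohort <- load_tma_cohort()
st <- tma_stats(cohort)
st$medians
#>   diploid aneuploid    normal carcinoma
#>    0.2673    0.3615    0.0395    0.2861
st$cutoff$cutoff        # 0.4489  (sensitivity 44%, specificity 89%)
st$cox
#> <cox_result> HR 12.959 (95% CI 2.352-71.399), p = 0.003259, 8 events, breslow ties
```

Thymosin β-4 immunopositivity is higher in aneuploid (median 0.3615) than
diploid (0.2673) carcinomas and far lower in normal mucosa (0.0395).
Dichotomizing the 18 tumor patients at the Youden-optimal cutoff
IP > 0.4489 yields 5 marker-positive patients — all of whom died — and a
13-fold hazard for overall survival.

A synthetic end-to-end discovery run:

```r
res <- run_pipeline(pipeline_config(seed = 7))
res$selected_peaks
#> "mz_2396" "mz_3376" "mz_4760" "mz_4976" "mz_6664" "mz_8580"
res$recognition$per_class     # 100 100 (cross-validated, % correct)
annotate_peaks(4977)$mz_4977  # Thymosin beta-4, |dm| = 0.49 Da
```

All six planted marker masses are recovered by ROC filtering (AUC > 0.75),
the selected supervised neural network classifies both tissue classes with
100% cross-validated recognition on this synthetic slide, and m/z 4,977
annotates to thymosin β-4 at ± 1 Da.

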