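Package: imsmarker
Title: Ploidy-Associated Biomarker Discovery from MALDI Imaging Mass
    Spectrometry with Clinical Survival Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open re-implementation of an analysis chain linking DNA image
    cytometry, MALDI imaging mass spectrometry (IMS) and tissue-microarray
    survival statistics for colorectal cancer. Provides Auer-type
    classification of per-nucleus DNA-content histograms (euploid versus
    aneuploid); a linear-TOF spectral preprocessing pipeline (mass-range
    restriction, spectral recalibration, total-ion-count normalization,
    convex-hull baseline correction, class-average peak picking and end-point
    peak-area integration); ROC-filtered supervised classification of tissue
    pixels (neural-network and weighted nearest-centroid models) with an
    unclassified rejection state; mass-tolerance peak-to-protein annotation;
    and the clinical statistics stage (group medians, Mann-Whitney U, Youden
    cutoff dichotomization, Kaplan-Meier, log-rank, univariate Cox and binary
    regression) together with the published 28-patient immunohistochemistry
    cohort as a fixture. A synthetic-data module generates imaging slides,
    DNA histograms and survival cohorts with the statistical structure the
    analysis assumes, so every stage is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nnet,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
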