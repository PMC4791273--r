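#' Pipeline configuration
#'
#' One flat object holding every stage default: observation mass range,
#' recalibration shift cap, baseline flatness, peak-picking SNR, ROC AUC
#' threshold, classifier kinds, confidence threshold, Cox tie handling,
#' annotation tolerance, the seed, and the output directory. Unknown keys
#' are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    mass_range = c(2000, 25000),
    max_shift_ppm = 1000,
    flatness = 0.8,
    snr_threshold = 3,
    auc_threshold = 0.75,
    classifier_kinds = c("snn", "quick"),
    confidence_threshold = 0.5,
    cv_folds = 5L,
    ties_method = "breslow",
    annotation_tol = 1,
    seed = 1L,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  }
  structure(utils::modifyList(defaults, dots), class = "pipeline_config")
}

#' Run the full analysis chain
#'
#' Executes the pipeline end to end on a slide (by default a generated
#' synthetic two-class slide), training ROIs and the clinical cohort:
#' spectral preprocessing, per-peak ROC filtering, model training and
#' selection by cross-validated recognition capability, whole-slide
#' classification, peak annotation against the protein lookup table, and
#' the clinical-statistics stage on the cohort. Every stage appends a log
#' line with its parameters; TSV artifacts are written when
#' `config$out_dir` is set. Identical config + seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param slide optional list `(dataset, truth)` as from
#'   [generate_ims_slide()]; default generates one from `slide_spec_args`.
#' @param slide_spec_args arguments for [slide_spec()] when generating.
#' @param cohort cohort data.frame; default [load_tma_cohort()].
#' @return list with `preprocessed`, `windows`, `roc`, `selected_peaks`,
#'   `model`, `recognition`, `map`, `annotation`, `clinical`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), slide = NULL,
                         slide_spec_args = list(), cohort = load_tma_cohort()) {
  stopifnot(inherits(config, "pipeline_config"))
  logline <- character()
  say <- function(fmt, ...) logline <<- c(logline, sprintf(fmt, ...))

  if (is.null(slide)) {
    args <- utils::modifyList(
      list(seed = config$seed,
           mass_range = config$mass_range,
           grid_shape = c(16L, 8L), mz_step = 4,
           null_pixel_fraction = 0.05),
      slide_spec_args)
    slide <- generate_ims_slide(do.call(slide_spec, args))
    say("simulate: synthetic slide, seed=%d", config$seed)
  }
  ds <- preprocess_ims(slide$dataset, mass_range = config$mass_range,
                       max_shift_ppm = config$max_shift_ppm,
                       flatness = config$flatness)
  say("preprocess: %d retained / %d excluded", length(ds$spectra), nrow(ds$excluded))

  # class-average peak picking on the training ROIs (the planted regions)
  truth <- slide$truth
  classes <- unique(truth$label)
  retained <- paste(ds$coords$x, ds$coords$y)
  avg_windows <- list()
  for (cl in classes) {
    idx <- which(retained %in% paste(truth$x[truth$label == cl],
                                     truth$y[truth$label == cl]))
    if (length(idx)) {
      avg <- class_average(ds$spectra[idx])
      avg_windows <- c(avg_windows, pick_peaks(avg, config$snr_threshold))
    }
  }
  # merge windows picked on different class averages (same underlying peak)
  centers <- vapply(avg_windows, `[[`, numeric(1), "center_mz")
  windows <- avg_windows[!duplicated(round(centers))]
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "center_mz"))]
  say("peak picking: %d windows", length(windows))

  rois <- lapply(classes, function(cl) {
    ims_roi(cl, truth[truth$label == cl, c("x", "y")])
  })
  mat <- extract_roi_matrix(ds, rois, windows)
  cls <- attr(mat, "row_class")
  rocs <- lapply(colnames(mat), function(lab) {
    roc_auc(mat[, lab], cls, peak_label = lab)
  })
  selected <- select_discriminative(rocs, config$auc_threshold)
  say("roc filter: %d/%d peaks with AUC > %g", length(selected), ncol(mat),
      config$auc_threshold)
  feat <- if (length(selected) >= 2L) selected else colnames(mat)
  sub <- mat[, feat, drop = FALSE]
  attr(sub, "row_class") <- cls

  candidates <- lapply(config$classifier_kinds, function(k) {
    train_model(sub, cls, kind = k, seed = config$seed,
                confidence_threshold = config$confidence_threshold)
  })
  model <- select_best_model(candidates, sub, cls, folds = config$cv_folds)
  rec <- attr(model, "recognition")
  say("model selection: %s, recognition %.1f%%", model$kind, rec$overall)

  wsel <- windows[vapply(windows, `[[`, character(1), "label") %in% feat]
  map <- classify_map(model, ds, wsel)
  say("classification map: %d/%d pixels assigned",
      sum(map$class != "UNCLASSIFIED"), nrow(map))

  ann <- annotate_peaks(vapply(wsel, `[[`, numeric(1), "center_mz"),
                        tol = config$annotation_tol)
  clinical <- tma_stats(cohort, ties_method = config$ties_method)
  say("clinical: HR %.3f (%.3f-%.3f)", clinical$cox$hr, clinical$cox$ci_low,
      clinical$cox$ci_high)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(map), file.path(config$out_dir, "segmentation_map.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(peak = vapply(rocs, `[[`, character(1), "peak_label"),
                                  auc = vapply(rocs, `[[`, numeric(1), "auc"),
                                  selected = vapply(rocs, `[[`, character(1), "peak_label") %in% selected),
                       file.path(config$out_dir, "peak_roc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(ds$log, logline), file.path(config$out_dir, "pipeline.log"))
  }

  list(preprocessed = ds, windows = windows, roc = rocs,
       selected_peaks = selected, model = model, recognition = rec,
       map = map, annotation = ann, clinical = clinical,
       log = c(ds$log, logline))
}
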