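#' Define a region of interest on a slide
#'
#' @param label class name, e.g. `"normal mucosa"`, `"diploid"`,
#'   `"aneuploid"`.
#' @param pixels two-column matrix or data.frame of `(x, y)` grid
#'   coordinates (0-based).
#' @return an object of class `ims_roi`.
#' @export
ims_roi <- function(label, pixels) {
  if (!nzchar(label)) stopf("ROI label must be nonempty")
  pixels <- as.matrix(pixels)[, 1:2, drop = FALSE]
  storage.mode(pixels) <- "integer"
  if (!nrow(pixels)) stopf("ROI '%s' is empty", label)
  structure(list(label = label, pixels = pixels), class = "ims_roi")
}

#' Extract a labelled peak matrix from ROI pixels
#'
#' Restricts a peak matrix to ROI pixels and labels each row with its ROI
#' class. Pixels excluded upstream (e.g. null spectra) are absent from the
#' result; the attribute `dropped` records them.
#'
#' @param ds a preprocessed [ims_dataset()].
#' @param rois list of [ims_roi()]; must be pairwise disjoint and within
#'   the grid.
#' @param windows list of [peak_window()].
#' @return peak matrix with attribute `row_class` (factor, one level per
#'   ROI label) and `dropped` (data.frame of ROI pixels not retained).
#' @export
extract_roi_matrix <- function(ds, rois, windows) {
  keys <- unlist(lapply(rois, function(r) paste(r$pixels[, 1], r$pixels[, 2])))
  if (anyDuplicated(keys)) stopf("ROIs overlap")
  for (r in rois) {
    if (any(r$pixels < 0) || any(r$pixels[, 1] >= ds$grid_shape[1]) ||
        any(r$pixels[, 2] >= ds$grid_shape[2])) {
      stopf("ROI '%s' extends outside the grid", r$label)
    }
  }
  full <- build_peak_matrix(ds, windows)
  retained <- paste(ds$coords$x, ds$coords$y)
  rows <- integer(); cls <- character()
  dropped <- data.frame(x = integer(), y = integer(), label = character())
  for (r in rois) {
    want <- paste(r$pixels[, 1], r$pixels[, 2])
    hit <- match(want, retained)
    miss <- is.na(hit)
    if (any(miss)) {
      dropped <- rbind(dropped, data.frame(x = r$pixels[miss, 1],
                                           y = r$pixels[miss, 2],
                                           label = r$label))
    }
    rows <- c(rows, hit[!miss])
    cls <- c(cls, rep(r$label, sum(!miss)))
  }
  out <- full[rows, , drop = FALSE]
  attr(out, "coords") <- ds$coords[rows, , drop = FALSE]
  attr(out, "row_class") <- factor(cls)
  attr(out, "dropped") <- dropped
  out
}

#' ROC area under the curve for one peak
#'
#' Rank-based AUC: (concordant pairs + half the ties) over all
#' positive-negative pairs. The positive class defaults to the class with
#' the higher mean value; the reported AUC is never flipped to
#' `max(auc, 1 - auc)`.
#'
#' @param values numeric peak areas.
#' @param labels two-level factor/vector of class labels.
#' @param positive positive-class label; default = higher-mean class.
#' @param peak_label carried through into the result.
#' @return list with `peak_label`, `auc`, `positive`.
#' @export
roc_auc <- function(values, labels, positive = NULL, peak_label = "") {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stopf("roc_auc needs exactly two classes, got %d", length(lev))
  if (is.null(positive)) {
    means <- tapply(values, labels, mean)
    positive <- names(means)[which.max(means)]
  }
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values)  # midranks handle ties as half-concordant pairs
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(peak_label = peak_label, auc = auc, positive = positive)
}

#' Select discriminative peaks by AUC threshold
#'
#' @param rocs list of [roc_auc()] results (or a named numeric vector of
#'   AUCs).
#' @param threshold strict lower bound on AUC (default 0.75).
#' @return character vector of peak labels with `auc > threshold`.
#' @export
select_discriminative <- function(rocs, threshold = 0.75) {
  if (is.numeric(rocs)) {
    rocs <- lapply(names(rocs), function(nm) list(peak_label = nm, auc = rocs[[nm]]))
  }
  labs <- vapply(rocs, `[[`, character(1), "peak_label")
  aucs <- vapply(rocs, `[[`, numeric(1), "auc")
  labs[aucs > threshold]
}

# per-feature between/within class variance ratio (the quick classifier's
# univariate weights, normalized to sum 1)
bw_weights <- function(x, y) {
  y <- factor(y)
  overall <- colMeans(x)
  k <- nlevels(y)
  b <- numeric(ncol(x)); w <- numeric(ncol(x))
  for (lev in levels(y)) {
    xi <- x[y == lev, , drop = FALSE]
    ni <- nrow(xi)
    b <- b + ni * (colMeans(xi) - overall)^2
    w <- w + colSums(sweep(xi, 2, colMeans(xi))^2)
  }
  b <- b / (k - 1)
  w <- w / (nrow(x) - k)
  # zero within-class variance = perfectly reliable feature, not a useless one
  ratio <- b / pmax(w, 1e-12 * max(c(b, 1)))
  if (sum(ratio) == 0) ratio <- rep(1, length(ratio))
  ratio / sum(ratio)
}

#' Train a pixel classifier on a labelled peak matrix
#'
#' Two model kinds mirror the classification software the workflow
#' replicates:
#' \describe{
#'   \item{`"snn"`}{a supervised neural network — single-hidden-layer
#'     feed-forward net (hidden size `2 * n_peaks`, logistic activations,
#'     softmax output, full-batch BFGS training) on standardized peak
#'     areas, deterministic given `seed`.}
#'   \item{`"quick"`}{a weighted nearest-centroid classifier whose
#'     per-peak weights are the normalized between/within class variance
#'     ratios.}
#' }
#' Both store normalized per-peak importance weights.
#'
#' @param matrix peak matrix (rows = spectra, columns = peaks).
#' @param row_class class label per row (taken from
#'   `attr(matrix, "row_class")` if missing); >= 2 classes with >= 5 rows
#'   each.
#' @param kind `"snn"` or `"quick"`.
#' @param seed RNG seed for network initialization.
#' @param confidence_threshold rejection threshold on the top-class
#'   confidence (default 0.5); pixels below it are left unclassified.
#' @param hidden_size hidden units for the SNN (default `2 * n_peaks`).
#' @param maxit,reltol SNN optimizer controls.
#' @return an object of class `ims_model`.
#' @export
train_model <- function(matrix, row_class = attr(matrix, "row_class"),
                        kind = c("snn", "quick"), seed = 1L,
                        confidence_threshold = 0.5,
                        hidden_size = 2L * ncol(matrix),
                        maxit = 500L, reltol = 1e-10) {
  kind <- match.arg(kind)
  y <- factor(row_class)
  x <- as.matrix(matrix)
  if (nlevels(y) < 2L) stopf("training needs >= 2 classes")
  if (any(table(y) < 5L)) stopf("every class needs >= 5 training rows")
  if (all(apply(x, 2, stats::var) == 0)) {
    stopf("degenerate training data: zero variance in every feature")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  weights <- bw_weights(xs, y)
  fit <- if (kind == "snn") {
    targets <- nnet::class.ind(y)
    with_seed(seed,
      nnet::nnet(xs, targets, size = hidden_size, softmax = TRUE,
                 maxit = maxit, reltol = reltol, decay = 1e-4,
                 trace = FALSE, MaxNWts = 1e5))
  } else {
    t(vapply(levels(y), function(lev) colMeans(xs[y == lev, , drop = FALSE]),
             numeric(ncol(xs))))
  }
  structure(list(kind = kind, peak_labels = colnames(x),
                 center = center, scale = scale, weights = weights,
                 fit = fit, classes = levels(y),
                 confidence_threshold = confidence_threshold,
                 seed = as.integer(seed)),
            class = "ims_model")
}

#' @export
print.ims_model <- function(x, ...) {
  cat(sprintf("<ims_model> kind=%s, %d peaks, classes: %s, confidence threshold %.2f\n",
              x$kind, length(x$peak_labels), paste(x$classes, collapse = " | "),
              x$confidence_threshold))
  invisible(x)
}

#' Predict classes and confidences from a trained model
#'
#' @param object an `ims_model`.
#' @param newdata peak matrix with the model's peak columns.
#' @param ... unused.
#' @return data.frame with `class` (argmax label, no rejection applied) and
#'   `confidence` (top-class posterior).
#' @export
predict.ims_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$peak_labels, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  post <- if (object$kind == "snn") {
    p <- stats::predict(object$fit, xs)
    if (is.null(dim(p))) p <- cbind(p, 1 - p)
    p
  } else {
    # softmax over negative weighted squared distances to the centroids
    d <- vapply(seq_along(object$classes), function(k) {
      rowSums(sweep(sweep(xs, 2, object$fit[k, ])^2, 2, object$weights, "*"))
    }, numeric(nrow(xs)))
    d <- matrix(d, nrow = nrow(xs))
    e <- exp(-(d - apply(d, 1, min)))
    e / rowSums(e)
  }
  top <- max.col(post, ties.method = "first")
  data.frame(class = object$classes[top],
             confidence = post[cbind(seq_len(nrow(post)), top)])
}

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated recognition capability
#'
#' Stratified k-fold cross-validation of a model specification, reporting
#' the per-class correct-classification percentage and their mean — the
#' model-selection statistic of the workflow.
#'
#' @param model an `ims_model` (its kind, seed and hyper-parameters are
#'   re-trained per fold).
#' @param matrix labelled peak matrix.
#' @param row_class class label per row (default from attribute).
#' @param folds number of folds (default 5); must not exceed the smallest
#'   class.
#' @return list with `per_class` (named percentages) and `overall` (their
#'   mean).
#' @export
recognition_capability <- function(model, matrix,
                                   row_class = attr(matrix, "row_class"),
                                   folds = 5L) {
  y <- factor(row_class)
  if (!all(model$classes %in% levels(y))) {
    stopf("labelled rows must cover all model classes")
  }
  if (folds > min(table(y))) {
    stopf("fold count (%d) exceeds the smallest class (%d)", folds, min(table(y)))
  }
  x <- as.matrix(matrix)
  assign <- stratified_folds(y, folds, model$seed)
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    tr <- assign != f
    m <- train_model(x[tr, , drop = FALSE], y[tr], kind = model$kind,
                     seed = model$seed,
                     confidence_threshold = model$confidence_threshold)
    pred[!tr] <- predict(m, x[!tr, , drop = FALSE])$class
  }
  per_class <- vapply(levels(y), function(lev) {
    100 * mean(pred[y == lev] == lev)
  }, numeric(1))
  list(per_class = per_class, overall = mean(per_class))
}

#' Select the model with the higher recognition capability
#'
#' Ties break toward the supervised neural network.
#'
#' @param candidates nonempty list of `ims_model`s.
#' @param matrix,row_class,folds passed to [recognition_capability()].
#' @return the winning `ims_model`, with attribute `recognition` holding
#'   its cross-validated rates.
#' @export
select_best_model <- function(candidates, matrix,
                              row_class = attr(matrix, "row_class"),
                              folds = 5L) {
  if (!length(candidates)) stopf("no candidate models")
  recs <- lapply(candidates, recognition_capability, matrix = matrix,
                 row_class = row_class, folds = folds)
  overall <- vapply(recs, `[[`, numeric(1), "overall")
  is_snn <- vapply(candidates, function(m) m$kind == "snn", logical(1))
  best <- order(-overall, !is_snn)[1]
  out <- candidates[[best]]
  attr(out, "recognition") <- recs[[best]]
  out
}

#' Classify every pixel of a slide
#'
#' Applies a trained model to each retained pixel's peak areas; pixels
#' whose top-class confidence falls below the model's threshold, and
#' pixels excluded upstream, are left `UNCLASSIFIED` (the red areas of a
#' colour-coded slide depiction).
#'
#' @param model an `ims_model`.
#' @param ds a preprocessed [ims_dataset()].
#' @param windows list of [peak_window()] matching the model's features.
#' @return a `segmentation_map`: data.frame with one row per grid pixel
#'   (`x`, `y`, `class`, `confidence`, `reason`); `class` is a label or
#'   `"UNCLASSIFIED"`.
#' @export
classify_map <- function(model, ds, windows) {
  labels <- vapply(windows, `[[`, character(1), "label")
  if (!setequal(labels, model$peak_labels)) {
    stopf("windows do not match the model's peak features")
  }
  grid <- expand.grid(x = 0:(ds$grid_shape[1] - 1L),
                      y = 0:(ds$grid_shape[2] - 1L))
  grid$class <- "UNCLASSIFIED"
  grid$confidence <- NA_real_
  grid$reason <- "not acquired"
  if (length(ds$spectra)) {
    m <- build_peak_matrix(ds, windows)
    pr <- predict(model, m)
    at <- match(paste(ds$coords$x, ds$coords$y), paste(grid$x, grid$y))
    accept <- pr$confidence >= model$confidence_threshold &
      model$confidence_threshold < 1
    grid$class[at] <- ifelse(accept, pr$class, "UNCLASSIFIED")
    grid$confidence[at] <- pr$confidence
    grid$reason[at] <- ifelse(accept, "", "confidence below threshold")
  }
  if (nrow(ds$excluded)) {
    at <- match(paste(ds$excluded$x, ds$excluded$y), paste(grid$x, grid$y))
    grid$reason[at] <- ds$excluded$reason
  }
  structure(grid, class = c("segmentation_map", "data.frame"),
            grid_shape = ds$grid_shape)
}

#' Write a segmentation map as a colour-coded PNG
#'
#' Classes get a fixed palette; unclassified pixels are red, matching the
#' conventional colour-encoded slide depiction. Requires the `png` package.
#'
#' @param map a `segmentation_map`.
#' @param path output file.
#' @param palette named vector of colours per class; unnamed classes cycle
#'   through a default palette.
#' @return `path`, invisibly.
#' @export
write_segmentation_png <- function(map, path, palette = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("the 'png' package is required to write PNG maps")
  }
  shape <- attr(map, "grid_shape")
  classes <- setdiff(unique(map$class), "UNCLASSIFIED")
  defaults <- c("#2ca02c", "#9467bd", "#1f77b4", "#ff7f0e", "#8c564b")
  if (is.null(palette)) {
    palette <- stats::setNames(defaults[seq_along(classes)], classes)
  }
  palette <- c(palette, UNCLASSIFIED = "#d62728")
  img <- array(0, dim = c(shape[2], shape[1], 3))
  rgb <- grDevices::col2rgb(palette[map$class]) / 255
  for (ch in 1:3) {
    img[cbind(map$y + 1L, map$x + 1L, ch)] <- rgb[ch, ]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Annotate peaks against a protein-mass table
#'
#' For each query peak, returns every protein whose mass lies within
#' `tol` Da (the conventional database mass tolerance of +/- 1 Da), sorted
#' by mass difference. Table rows may give either a single `mass_da` or a
#' printed range `mass_lo_da`/`mass_hi_da`; the difference to a range is
#' the distance to its nearest bound (0 inside the range).
#'
#' @param peaks numeric vector of query m/z values, optionally named.
#' @param protein_table data.frame with columns `name`, `accession`, and
#'   `mass_da` or `mass_lo_da` + `mass_hi_da`; default is the bundled
#'   lookup fixture ([load_protein_table()]).
#' @param tol mass tolerance in Da (default 1).
#' @return named list (one element per peak) of data.frames `name`,
#'   `accession`, `mass_da`, `delta_da`; empty data.frames allowed.
#' @export
annotate_peaks <- function(peaks, protein_table = load_protein_table(), tol = 1) {
  if (any(peaks <= 0)) stopf("query masses must be positive")
  tab <- protein_table
  if (!("mass_lo_da" %in% names(tab))) {
    tab$mass_lo_da <- tab$mass_da
    tab$mass_hi_da <- tab$mass_da
  }
  if (!("mass_da" %in% names(tab))) {
    tab$mass_da <- (tab$mass_lo_da + tab$mass_hi_da) / 2
  }
  nms <- if (is.null(names(peaks))) sprintf("mz_%.0f", peaks) else names(peaks)
  out <- lapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    delta <- pmax(0, pmax(tab$mass_lo_da - p, p - tab$mass_hi_da))
    hit <- delta <= tol
    res <- data.frame(name = tab$name[hit], accession = tab$accession[hit],
                      mass_da = tab$mass_da[hit], delta_da = delta[hit])
    res[order(res$delta_da), , drop = FALSE]
  })
  stats::setNames(out, nms)
}
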