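# a linearly separable labelled peak matrix built from the generator
separable_matrix <- function(seed = 1L, noise_sd = 1, cv = 0.2, ratio = 2,
                             grid_shape = c(10L, 6L)) {
  out <- generate_ims_slide(small_slide_spec(seed = seed, noise_sd = noise_sd,
                                             cv = cv, ratio = ratio,
                                             grid_shape = grid_shape))
  ds <- preprocess_ims(out$dataset)
  windows <- lapply(c(2395, 3376, 4761, 4977, 6663, 8581), function(p) {
    peak_window(p, p - 25, p + 25)
  })
  rois <- lapply(split(out$truth, out$truth$label), function(tr) {
    ims_roi(tr$label[1], tr[, c("x", "y")])
  })
  list(matrix = extract_roi_matrix(ds, rois, windows), ds = ds,
       windows = windows, truth = out$truth)
}

test_that("ROI extraction labels rows, rejects overlap, and drops excluded pixels", {
  out <- generate_ims_slide(small_slide_spec(seed = 51, null_pixel_fraction = 0.1))
  ds <- preprocess_ims(out$dataset)
  windows <- list(peak_window(4977, 4950, 5004))
  r1 <- ims_roi("diploid", expand.grid(x = 0:4, y = 0:1))
  r2 <- ims_roi("aneuploid", expand.grid(x = 5:9, y = 0:1))
  m <- extract_roi_matrix(ds, list(r1, r2), windows)
  dropped <- attr(m, "dropped")
  expect_equal(nrow(m) + nrow(dropped), 20L)
  expect_equal(as.character(unique(attr(m, "row_class"))) %in% c("diploid", "aneuploid"),
               c(TRUE, TRUE))
  # every dropped ROI pixel is one the preprocessing excluded
  if (nrow(dropped)) {
    expect_true(all(paste(dropped$x, dropped$y) %in%
                    paste(ds$excluded$x, ds$excluded$y)))
  }
  overlap <- ims_roi("aneuploid", expand.grid(x = 4:6, y = 0:1))
  expect_error(extract_roi_matrix(ds, list(r1, overlap), windows), "overlap")
  outside <- ims_roi("x", cbind(99, 99))
  expect_error(extract_roi_matrix(ds, list(outside), windows), "outside")
})

test_that("rank-based AUC equals brute-force pair enumeration", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c("a", "b"), each = 4), positive = "b")$auc, 0.5)

  # explicit 9-pair enumeration: 1,2,3 vs 2,4,5
  vals <- c(1, 2, 3, 2, 4, 5)
  labs <- rep(c("neg", "pos"), each = 3)
  expect_equal(roc_auc(vals, labs, positive = "pos")$auc,
               brute_auc(vals, labs, "pos"))
  expect_equal(brute_auc(vals, labs, "pos"), 7.5 / 9)

  set.seed(52)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    v <- sample(1:8, n, replace = TRUE)  # heavy ties
    l <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    got <- roc_auc(v, l, positive = "b")$auc
    expect_equal(got, brute_auc(v, l, "b"))
    # label-swap symmetry
    expect_equal(roc_auc(v, l, positive = "a")$auc, 1 - got)
  }
  expect_error(roc_auc(1:5, rep("a", 5)), "two classes")
})

test_that("peak selection by AUC is strict and reproduces the published picks", {
  tab <- load_snn_peak_table("diploid_vs_aneuploid")
  aucs <- setNames(ifelse(is.na(tab$auc), 0.5, tab$auc),
                   sprintf("mz_%d", tab$peak_mz))
  expect_setequal(select_discriminative(aucs), c("mz_2395", "mz_4977"))
  expect_length(select_discriminative(c(a = 0.75, b = 0.75)), 0L)
  expect_length(select_discriminative(numeric()), 0L)
})

test_that("both model kinds reach 100% training accuracy on separable data", {
  sep <- separable_matrix(seed = 53)
  for (kind in c("snn", "quick")) {
    m <- train_model(sep$matrix, kind = kind, seed = 3)
    pred <- predict(m, sep$matrix)
    expect_equal(mean(pred$class == attr(sep$matrix, "row_class")), 1,
                 info = kind)
    expect_true(all(m$weights >= 0))
    expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  }
})

test_that("training is deterministic given the seed", {
  sep <- separable_matrix(seed = 54)
  m1 <- train_model(sep$matrix, kind = "snn", seed = 5)
  m2 <- train_model(sep$matrix, kind = "snn", seed = 5)
  expect_identical(m1$fit$wts, m2$fit$wts)
})

test_that("permuted labels drop cross-validated recognition to chance", {
  sep <- separable_matrix(seed = 55)
  y <- attr(sep$matrix, "row_class")
  set.seed(56)
  yperm <- sample(y)
  m <- train_model(sep$matrix, yperm, kind = "quick", seed = 6)
  rec <- recognition_capability(m, sep$matrix, yperm)
  # chance = 50% for two balanced classes; binomial error on 60 rows
  expect_lt(abs(rec$overall - 50), 20)
})

test_that("degenerate all-constant training data is rejected", {
  x <- matrix(1, nrow = 20, ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(train_model(x, rep(c("u", "v"), each = 10), kind = "quick"),
               "degenerate")
})

test_that("recognition capability is stratified, bounded, and errors on tiny folds", {
  sep <- separable_matrix(seed = 57)
  m <- train_model(sep$matrix, kind = "quick", seed = 7)
  rec <- recognition_capability(m, sep$matrix)
  expect_named(rec$per_class, levels(attr(sep$matrix, "row_class")))
  expect_true(all(rec$per_class >= 0 & rec$per_class <= 100))
  expect_equal(rec$overall, mean(rec$per_class))
  expect_error(recognition_capability(m, sep$matrix, folds = 1000), "fold count")
})

test_that("model selection is argmax on recognition with SNN tie-break", {
  sep <- separable_matrix(seed = 58)
  snn <- train_model(sep$matrix, kind = "snn", seed = 8)
  quick <- train_model(sep$matrix, kind = "quick", seed = 8)
  one <- select_best_model(list(quick), sep$matrix)
  expect_equal(one$kind, "quick")
  # both reach 100% on separable data -> tie resolves to the SNN
  best <- select_best_model(list(quick, snn), sep$matrix)
  expect_equal(best$kind, "snn")
  expect_error(select_best_model(list(), sep$matrix), "no candidate")
})

test_that("zero-noise slides are segmented pixel-perfectly with no rejections", {
  out <- generate_ims_slide(small_slide_spec(seed = 59, noise_sd = 0,
                                             ppm_jitter_sd = 0, cv = 0))
  ds <- preprocess_ims(out$dataset, align = FALSE)
  windows <- lapply(c(2395, 4977), function(p) peak_window(p, p - 25, p + 25))
  rois <- lapply(split(out$truth, out$truth$label), function(tr) {
    ims_roi(tr$label[1], tr[, c("x", "y")])
  })
  mat <- extract_roi_matrix(ds, rois, windows)
  model <- train_model(mat, kind = "quick", seed = 9)
  map <- classify_map(model, ds, windows)
  truth_lab <- out$truth$label[match(paste(map$x, map$y),
                                     paste(out$truth$x, out$truth$y))]
  expect_identical(map$class, truth_lab)
  expect_equal(sum(map$class == "UNCLASSIFIED"), 0L)
  # every grid pixel appears exactly once
  expect_equal(nrow(map), prod(out$dataset$grid_shape))
  expect_false(anyDuplicated(paste(map$x, map$y)) > 0)
})

test_that("confidence threshold 1 rejects everything; null pixels carry their reason", {
  out <- generate_ims_slide(small_slide_spec(seed = 60, null_pixel_fraction = 0.15))
  ds <- preprocess_ims(out$dataset)
  windows <- lapply(c(2395, 4977), function(p) peak_window(p, p - 25, p + 25))
  rois <- lapply(split(out$truth, out$truth$label), function(tr) {
    ims_roi(tr$label[1], tr[, c("x", "y")])
  })
  mat <- extract_roi_matrix(ds, rois, windows)
  model <- train_model(mat, kind = "quick", seed = 10, confidence_threshold = 1)
  map <- classify_map(model, ds, windows)
  expect_true(all(map$class == "UNCLASSIFIED"))

  model2 <- train_model(mat, kind = "quick", seed = 10)
  map2 <- classify_map(model2, ds, windows)
  nulls <- ds$excluded[ds$excluded$reason == "null spectrum", ]
  at <- match(paste(nulls$x, nulls$y), paste(map2$x, map2$y))
  expect_true(all(map2$class[at] == "UNCLASSIFIED"))
  expect_true(all(map2$reason[at] == "null spectrum"))
})

test_that("annotation hits thymosin beta-4 at 4,977 and 4,761 and nothing at 5,150", {
  ann <- annotate_peaks(c(4977, 4761, 5150))
  expect_equal(ann$mz_4977$name, "Thymosin beta-4")
  expect_equal(ann$mz_4977$delta_da, 0.49)
  expect_equal(ann$mz_4761$name, "Thymosin beta-4")
  expect_equal(ann$mz_4761$mass_da, 4761.42)
  expect_equal(nrow(ann$mz_5150), 0L)

  # widening the tolerance never removes a hit
  narrow <- annotate_peaks(c(2434, 3376, 4977), tol = 0.5)
  wide <- annotate_peaks(c(2434, 3376, 4977), tol = 2)
  for (nm in names(narrow)) {
    expect_true(all(narrow[[nm]]$accession %in% wide[[nm]]$accession))
  }
  expect_error(annotate_peaks(-5), "positive")
})
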