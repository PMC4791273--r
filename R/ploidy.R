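#' Construct a per-nucleus DNA-content histogram
#'
#' Holds one DNA-content value per measured nucleus, in c-units (2c = the
#' normal diploid genome content, anchored by lymphocyte staining
#' controls). Fewer than `min_cells` nuclei sets a quality flag — the
#' 500-nuclei criterion is an acquisition guideline, not a hard error.
#'
#' @param c_values numeric, DNA content per nucleus in c-units (> 0).
#' @param source_id free-text sample identifier.
#' @param min_cells minimum nucleus count before the low-cell-count quality
#'   flag is raised (default 500).
#' @return an object of class `dna_histogram`.
#' @export
dna_histogram <- function(c_values, source_id = "", min_cells = 500L) {
  c_values <- as.numeric(c_values)
  if (!length(c_values)) stopf("a DNA histogram needs at least one nucleus")
  if (any(!is.finite(c_values)) || any(c_values <= 0)) {
    stopf("all c-values must be finite and > 0")
  }
  structure(list(c_values = c_values, n_cells = length(c_values),
                 source_id = source_id,
                 low_cell_count = length(c_values) < min_cells),
            class = "dna_histogram")
}

#' @export
print.dna_histogram <- function(x, ...) {
  cat(sprintf("<dna_histogram> %s%d nuclei, median %.2fc%s\n",
              if (nzchar(x$source_id)) paste0(x$source_id, ": ") else "",
              x$n_cells, stats::median(x$c_values),
              if (x$low_cell_count) " [low cell count]" else ""))
  invisible(x)
}

#' Convert integrated optical densities to c-values
#'
#' DNA values are expressed relative to the lymphocyte staining controls,
#' which are assigned the value 2c (normal diploid content):
#' `c = 2 * iod / control_iod_mean`.
#'
#' @param raw_iod numeric, integrated optical densities (>= 0).
#' @param control_iod_mean mean IOD of the lymphocyte controls (> 0).
#' @return c-values, order preserved.
#' @export
#' @examples
#' to_c_values(c(50, 100, 250), 100)  # 1, 2, 5
to_c_values <- function(raw_iod, control_iod_mean) {
  assert_number(control_iod_mean, "control_iod_mean", lower = 1e-300)
  if (any(raw_iod < 0)) stopf("raw IOD values must be >= 0")
  2 * raw_iod / control_iod_mean
}

#' Detect stem lines in a DNA histogram
#'
#' Bins the c-values at `bin_width`, finds local maxima holding at least
#' `min_peak_fraction` of the cells, merges adjacent qualifying bins (ties),
#' and reports each stem line as the mean c-value of the cells in the
#' mode's bin neighbourhood, ascending, rounded to 2 decimals.
#'
#' @param hist a [dna_histogram()] or numeric vector of c-values.
#' @param bin_width histogram bin width in c-units (default 0.2).
#' @param min_peak_fraction minimum fraction of cells a modal bin must hold
#'   (default 0.05).
#' @return numeric vector of stem-line c-positions.
#' @export
detect_stem_lines <- function(hist, bin_width = 0.2, min_peak_fraction = 0.05) {
  v <- if (inherits(hist, "dna_histogram")) hist$c_values else as.numeric(hist)
  if (!length(v)) stopf("empty histogram")
  assert_number(bin_width, "bin_width", lower = 1e-12)
  breaks <- seq(0, max(v) + bin_width, by = bin_width)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  n <- length(counts)
  left <- c(0L, counts[-n])
  right <- c(counts[-1L], 0L)
  is_mode <- counts >= left & counts >= right &
    counts >= min_peak_fraction * length(v) & counts > 0L
  if (!any(is_mode)) {
    # degenerate spread: fall back to the global modal bin
    is_mode <- counts == max(counts) & counts > 0L
  }
  # merge runs of adjacent qualifying bins into one stem line
  idx <- which(is_mode)
  grp <- cumsum(c(1L, diff(idx) > 1L))
  pos <- vapply(split(idx, grp), function(bins) {
    lo <- breaks[min(bins)] - bin_width / 2
    hi <- breaks[max(bins) + 1L] + bin_width / 2
    mean(v[v >= lo & v <= hi])
  }, numeric(1))
  round_half_up(sort(unname(pos)), 2)
}

#' Fraction of nuclei exceeding a DNA-content threshold
#'
#' Strict-greater-than count divided by the total cell count, e.g. the
#' fraction of nuclei beyond the tetraploid region (> 4.5c).
#'
#' @param c_values numeric c-values or a [dna_histogram()].
#' @param threshold c-unit threshold (> 0), exceedance is strict.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' exceeding_fraction(c(1, 2, 3, 4, 5, 6), 4.5)  # 2/6
exceeding_fraction <- function(c_values, threshold) {
  v <- if (inherits(c_values, "dna_histogram")) c_values$c_values else as.numeric(c_values)
  if (!length(v)) stopf("empty histogram")
  assert_number(threshold, "threshold", lower = 1e-300)
  mean(v > threshold)
}

#' Classify a DNA histogram into Auer types I-IV
#'
#' Applies the histogram-type rules of DNA image cytometry: type I is a
#' single stem line in the diploid region (1.5-2.5c) with < 10% of cells
#' above 2.5c; type II has stem lines in the tetraploid region (3.5-4.5c)
#' and/or diploid region jointly holding > 90% of cells; type III is a
#' highly proliferating near-diploid population with cells spread between
#' the diploid and tetraploid regions and < 5% above 4.5c; type IV shows
#' increased (> 5%) and/or distinctly scattered DNA values above 4.5c.
#' Types I-III are euploid; type IV is aneuploid.
#'
#' The overlapping side-conditions are resolved by fixed precedence
#' IV, II, I, then III as the euploid fallback, so every histogram receives
#' exactly one type. The subjective "distinctly scattered" clause is an
#' optional second trigger (off by default): at least `scatter_min_count`
#' nuclei above 5c together with a histogram coefficient of variation above
#' `scatter_min_cv`.
#'
#' @param hist a [dna_histogram()] or numeric vector of c-values.
#' @param bin_width,min_peak_fraction passed to [detect_stem_lines()].
#' @param scatter_rule enable the "distinctly scattered" trigger.
#' @param scatter_min_count,scatter_min_cv parameters of that trigger.
#' @return an object of class `auer_result`: `auer_type` (`"I"`..`"IV"`),
#'   `ploidy_label` (`"euploid"`/`"aneuploid"`), `stem_lines`, the region
#'   fractions, `count_gt_5c`, and the `low_cell_count` quality flag.
#' @export
classify_auer <- function(hist, bin_width = 0.2, min_peak_fraction = 0.05,
                          scatter_rule = FALSE, scatter_min_count = 20L,
                          scatter_min_cv = 0.25) {
  if (!inherits(hist, "dna_histogram")) hist <- dna_histogram(hist)
  v <- hist$c_values
  sl <- detect_stem_lines(hist, bin_width, min_peak_fraction)
  frac_in <- function(lo, hi) mean(v >= lo & v <= hi)
  f_dip <- frac_in(1.5, 2.5)
  f_tet <- frac_in(3.5, 4.5)
  f_between <- mean(v > 2.5 & v < 3.5)
  f_gt25 <- exceeding_fraction(v, 2.5)
  f_gt45 <- exceeding_fraction(v, 4.5)
  n_gt5 <- sum(v > 5)
  scattered <- scatter_rule && n_gt5 >= scatter_min_count &&
    stats::sd(v) / mean(v) > scatter_min_cv
  type <-
    if (f_gt45 > 0.05 || scattered) {
      "IV"
    } else if (any(sl >= 3.5 & sl <= 4.5) && f_dip + f_tet > 0.9) {
      "II"
    } else if (all(sl >= 1.5 & sl <= 2.5) && f_gt25 < 0.10) {
      "I"
    } else {
      "III"
    }
  structure(list(auer_type = type,
                 ploidy_label = if (type == "IV") "aneuploid" else "euploid",
                 stem_lines = sl,
                 frac_gt_2_5c = f_gt25,
                 frac_diploid_region = f_dip,
                 frac_tetraploid_region = f_tet,
                 frac_between = f_between,
                 frac_gt_4_5c = f_gt45,
                 count_gt_4_5c = sum(v > 4.5),
                 count_gt_5c = n_gt5,
                 n_cells = hist$n_cells,
                 low_cell_count = hist$low_cell_count,
                 source_id = hist$source_id),
            class = "auer_result")
}

#' @export
print.auer_result <- function(x, ...) {
  cat(sprintf("<auer_result> type %s (%s), SL %s, >4.5c %.1f%%, 5c-Exc %d/%d%s\n",
              x$auer_type, x$ploidy_label,
              paste(sprintf("%.2f", x$stem_lines), collapse = " + "),
              100 * x$frac_gt_4_5c, x$count_gt_5c, x$n_cells,
              if (x$low_cell_count) " [low cell count]" else ""))
  invisible(x)
}

#' One-row data.frame report of an Auer classification
#'
#' @param x an `auer_result`.
#' @return data.frame with all result fields, suitable for [write.table()].
#' @export
auer_report <- function(x) {
  stopifnot(inherits(x, "auer_result"))
  data.frame(source_id = x$source_id, n_cells = x$n_cells,
             auer_type = x$auer_type, ploidy_label = x$ploidy_label,
             stem_lines = paste(sprintf("%.2f", x$stem_lines), collapse = " + "),
             frac_gt_2_5c = x$frac_gt_2_5c,
             frac_diploid_region = x$frac_diploid_region,
             frac_tetraploid_region = x$frac_tetraploid_region,
             frac_between = x$frac_between,
             frac_gt_4_5c = x$frac_gt_4_5c,
             count_gt_4_5c = x$count_gt_4_5c,
             count_gt_5c = x$count_gt_5c,
             low_cell_count = x$low_cell_count)
}
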