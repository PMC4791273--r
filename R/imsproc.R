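#' Restrict a spectrum to the observation mass range
#'
#' @param s an [ims_spectrum()].
#' @param lo,hi mass range bounds in Da (default 2000-25000, the linear-TOF
#'   observation range).
#' @return the spectrum with only points in `[lo, hi]`; an empty result
#'   carries attribute `null_spectrum = TRUE`.
#' @export
restrict_mass_range <- function(s, lo = 2000, hi = 25000) {
  if (lo >= hi) stopf("need lo < hi")
  keep <- s$mz >= lo & s$mz <= hi
  out <- ims_spectrum(s$mz[keep], s$intensity[keep], pixel = s$pixel)
  if (!any(keep)) attr(out, "null_spectrum") <- TRUE
  out
}

# lower convex hull of (x, y) points by Andrew's monotone chain;
# x must be strictly increasing; returns indices of the hull vertices
lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- hull[k - 1L]; b <- hull[k]
      # drop b if it lies on or above segment a -> i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0) {
        k <- k - 1L
      } else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

#' Convex-hull baseline correction
#'
#' Subtracts the lower convex hull of the spectrum's (m/z, intensity)
#' points, linearly interpolated between hull vertices. The `flatness`
#' parameter controls a pre-hull running-median smoothing with window
#' `(1 - flatness) * length(s)` (rounded down to odd); the hull is anchored
#' on the pointwise minimum of the raw and smoothed traces, which keeps
#' narrow peaks from pulling the baseline up while guaranteeing a baseline
#' nowhere above the raw signal. Correction is therefore non-negative
#' everywhere and exactly idempotent.
#'
#' @param s an [ims_spectrum()] with at least 3 points.
#' @param flatness smoothing knob in `[0, 1]`; 1 disables smoothing
#'   (default 0.8).
#' @return list with `spectrum` (corrected) and `baseline` (an
#'   [ims_spectrum()] holding the subtracted curve).
#' @export
baseline_convex_hull <- function(s, flatness = 0.8) {
  if (length(s$mz) < 3L) stopf("baseline correction needs >= 3 points")
  assert_number(flatness, "flatness", 0, 1)
  k <- floor((1 - flatness) * length(s$mz))
  if (k %% 2 == 0) k <- k - 1L
  anchor <- if (k >= 3) {
    pmin(stats::runmed(s$intensity, k, endrule = "keep"), s$intensity)
  } else {
    s$intensity
  }
  v <- lower_hull_indices(s$mz, anchor)
  base <- stats::approx(s$mz[v], anchor[v], xout = s$mz)$y
  corrected <- pmax(s$intensity - base, 0)
  list(spectrum = ims_spectrum(s$mz, corrected, pixel = s$pixel),
       baseline = ims_spectrum(s$mz, base, pixel = s$pixel))
}

#' Total-ion-count normalization
#'
#' Scales intensities so they sum to 1 over the observation range. A
#' spectrum whose TIC does not exceed `epsilon` is flagged for exclusion
#' ("null spectrum") and returned unscaled.
#'
#' @param s an [ims_spectrum()] restricted to the observation range.
#' @param epsilon TIC threshold below which the spectrum counts as null.
#' @return the normalized spectrum; a null spectrum carries attribute
#'   `exclude_reason = "null spectrum"`.
#' @export
tic_normalize <- function(s, epsilon = 0) {
  if (any(s$intensity < 0)) {
    stopf("negative intensities: TIC normalization expects raw or baseline-corrected non-negative spectra")
  }
  total <- tic(s)
  if (total <= epsilon) {
    attr(s, "exclude_reason") <- "null spectrum"
    return(s)
  }
  ims_spectrum(s$mz, s$intensity / total, pixel = s$pixel)
}

# local maxima indices of an intensity trace (strict on at least one side)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  i[y[i] >= y[i - 1L] & y[i] >= y[i + 1L] & (y[i] > y[i - 1L] | y[i] > y[i + 1L])]
}

# top-k most intense local maxima, as m/z positions
top_peaks <- function(s, k = 10L) {
  idx <- local_maxima(s$intensity)
  if (!length(idx)) return(numeric())
  idx <- idx[order(s$intensity[idx], decreasing = TRUE)]
  s$mz[utils::head(idx, k)]
}

#' Recalibrate spectra by alignment to a reference
#'
#' Estimates one multiplicative m/z correction factor per spectrum (a
#' global ppm shift) by matching its `top_k` most intense local maxima to
#' the reference's and taking the median reference/observed m/z ratio.
#' Spectra whose estimated absolute shift exceeds `max_shift_ppm` are
#' excluded ("shift over limit"), as are spectra with no matchable peaks.
#' Aligned spectra are resampled onto the reference m/z axis by linear
#' interpolation.
#'
#' @param spectra list of [ims_spectrum()].
#' @param reference an [ims_spectrum()] defining the target calibration.
#' @param max_shift_ppm maximum tolerated |shift| in ppm (default 1000).
#' @param top_k number of peaks used for matching (default 10).
#' @param match_window_ppm how far an observed peak may sit from a
#'   reference peak and still be considered the same species.
#' @return list with `spectra` (aligned, on the reference axis),
#'   `shifts_ppm` (applied shift per retained spectrum), and `excluded`
#'   (data.frame `index`, `reason`).
#' @export
recalibrate <- function(spectra, reference, max_shift_ppm = 1000, top_k = 10L,
                        match_window_ppm = 3 * max_shift_ppm) {
  if (!length(reference$mz)) stopf("empty reference spectrum")
  ref_peaks <- top_peaks(reference, top_k)
  aligned <- list()
  shifts <- numeric()
  excluded <- data.frame(index = integer(), reason = character())
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    obs <- top_peaks(s, top_k)
    ratios <- numeric()
    for (p in obs) {
      j <- which.min(abs(ref_peaks - p))
      if (length(j) && abs(ref_peaks[j] - p) / p <= match_window_ppm * 1e-6) {
        ratios <- c(ratios, ref_peaks[j] / p)
      }
    }
    if (!length(ratios)) {
      excluded <- rbind(excluded, data.frame(index = i, reason = "no matchable peaks"))
      next
    }
    factor <- stats::median(ratios)
    shift_ppm <- (factor - 1) * 1e6
    if (abs(shift_ppm) > max_shift_ppm) {
      excluded <- rbind(excluded, data.frame(index = i, reason = "shift over limit"))
      next
    }
    y <- stats::approx(s$mz * factor, s$intensity, xout = reference$mz,
                       yleft = 0, yright = 0)$y
    aligned <- c(aligned, list(ims_spectrum(reference$mz, y, pixel = s$pixel)))
    shifts <- c(shifts, shift_ppm)
  }
  list(spectra = aligned, shifts_ppm = shifts, excluded = excluded)
}

#' Pointwise average spectrum of a class
#'
#' @param spectra nonempty list of [ims_spectrum()] on a common m/z axis
#'   (spectra on other axes are resampled to the first by linear
#'   interpolation).
#' @return an [ims_spectrum()], the arithmetic mean.
#' @export
class_average <- function(spectra) {
  if (!length(spectra)) stopf("cannot average an empty list of spectra")
  mz <- spectra[[1]]$mz
  acc <- numeric(length(mz))
  for (s in spectra) {
    acc <- acc + if (length(s$mz) == length(mz) && isTRUE(all.equal(s$mz, mz))) {
      s$intensity
    } else {
      stats::approx(s$mz, s$intensity, xout = mz, yleft = 0, yright = 0)$y
    }
  }
  ims_spectrum(mz, acc / length(spectra))
}

#' Pick peaks on a class-average spectrum
#'
#' Local maxima whose apex exceeds `snr_threshold` times a robust noise
#' estimate (median absolute deviation of the corrected intensities,
#' scaled by 1.4826) become integration windows. The apex must also rise
#' at least that far above its flanking local minima (peak prominence),
#' which suppresses noise ripples riding the broad concave residuals a
#' convex-hull baseline cannot remove. Window bounds are the nearest
#' flanking local minima, so windows of distinct peaks do not overlap.
#'
#' @param avg a baseline-corrected [ims_spectrum()].
#' @param snr_threshold signal-to-noise cutoff (default 3).
#' @return list of [peak_window()]s, ascending in `center_mz`; empty for a
#'   flat spectrum.
#' @export
pick_peaks <- function(avg, snr_threshold = 3) {
  y <- avg$intensity
  apexes <- local_maxima(y)
  if (!length(apexes)) return(list())
  noise <- stats::mad(y)
  apexes <- apexes[y[apexes] > snr_threshold * noise & y[apexes] > 0]
  if (!length(apexes)) return(list())
  n <- length(y)
  bounds <- lapply(apexes, function(a) {
    l <- a
    while (l > 1L && y[l - 1L] <= y[l]) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] <= y[r]) r <- r + 1L
    prominence <- y[a] - max(y[l], y[r])
    if (prominence <= snr_threshold * noise && noise > 0) return(NULL)
    c(apex = a, lo = l, hi = r)
  })
  bounds <- do.call(rbind, bounds[!vapply(bounds, is.null, logical(1))])
  if (is.null(bounds)) return(list())
  # adjacent apexes inside one monotone run collapse to the same bounds;
  # keep the first apex per (lo, hi) pair, then order by position
  bounds <- bounds[!duplicated(bounds[, c("lo", "hi"), drop = FALSE]), , drop = FALSE]
  bounds <- bounds[order(bounds[, "apex"]), , drop = FALSE]
  # descending runs of neighbouring peaks may both claim a flat valley;
  # split shared territory at the deepest point between the two apexes
  if (nrow(bounds) > 1L) {
    for (i in seq_len(nrow(bounds) - 1L)) {
      if (bounds[i, "hi"] > bounds[i + 1L, "lo"]) {
        span <- bounds[i, "apex"]:bounds[i + 1L, "apex"]
        cut <- span[which.min(y[span])]
        bounds[i, "hi"] <- cut
        bounds[i + 1L, "lo"] <- cut
      }
    }
  }
  lapply(seq_len(nrow(bounds)), function(i) {
    peak_window(avg$mz[bounds[i, "apex"]], avg$mz[bounds[i, "lo"]],
                avg$mz[bounds[i, "hi"]])
  })
}

#' End-point level peak integration
#'
#' Trapezoidal integral of the intensity over the window minus the
#' trapezoidal integral of the chord joining the two endpoint intensities
#' (the "end-point level"), clamped at 0. Adding any affine function of
#' m/z across the window leaves the result unchanged.
#'
#' @param s an [ims_spectrum()].
#' @param w a [peak_window()] lying within the spectrum's m/z range.
#' @return integrated area (>= 0).
#' @export
integrate_endpoint <- function(s, w) {
  if (w$lo < min(s$mz) || w$hi > max(s$mz)) {
    stopf("window [%g, %g] outside spectrum range [%g, %g]",
          w$lo, w$hi, min(s$mz), max(s$mz))
  }
  idx <- which(s$mz >= w$lo & s$mz <= w$hi)
  if (length(idx) < 2L) return(0)
  x <- s$mz[idx]
  y <- s$intensity[idx]
  chord <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
  max(0, pracma::trapz(x, y - chord))
}

#' Build a peak matrix from a preprocessed dataset
#'
#' @param ds a preprocessed [ims_dataset()].
#' @param windows nonempty list of [peak_window()].
#' @return numeric matrix, one row per retained pixel (rownames `"x,y"`),
#'   one column per window label, values from [integrate_endpoint()];
#'   attribute `coords` holds the pixel coordinates.
#' @export
build_peak_matrix <- function(ds, windows) {
  if (!length(windows)) stopf("need at least one peak window")
  m <- matrix(0, nrow = length(ds$spectra), ncol = length(windows),
              dimnames = list(paste(ds$coords$x, ds$coords$y, sep = ","),
                              vapply(windows, `[[`, character(1), "label")))
  for (i in seq_along(ds$spectra)) {
    for (j in seq_along(windows)) {
      m[i, j] <- integrate_endpoint(ds$spectra[[i]], windows[[j]])
    }
  }
  attr(m, "coords") <- ds$coords
  m
}

#' Run the full spectral preprocessing chain on a dataset
#'
#' Fixed, logged order: mass-range restriction, recalibration by spectral
#' alignment against the slide mean spectrum, TIC normalization (with
#' exclusion of null spectra), convex-hull baseline correction. The null
#' threshold is `1e-6` times the slide's median TIC.
#'
#' @param ds an [ims_dataset()].
#' @param mass_range observation range `c(lo, hi)` Da.
#' @param max_shift_ppm recalibration shift cap (default 1000).
#' @param flatness baseline-flatness smoothing knob (default 0.8).
#' @param align skip the recalibration step when `FALSE` (already
#'   calibrated or single-spectrum data).
#' @return the preprocessed `ims_dataset`, with exclusions and a
#'   processing log recording every step and its parameters.
#' @export
preprocess_ims <- function(ds, mass_range = ds$mass_range,
                           max_shift_ppm = 1000, flatness = 0.8,
                           align = TRUE) {
  ds$spectra <- lapply(ds$spectra, restrict_mass_range,
                       lo = mass_range[1], hi = mass_range[2])
  ds$mass_range <- as.numeric(mass_range)
  ds <- log_step(ds, "restrict_mass_range lo=%g hi=%g", mass_range[1], mass_range[2])

  # null spectra must go before alignment: no peaks to match
  tics <- vapply(ds$spectra, tic, numeric(1))
  eps <- 1e-6 * stats::median(tics)
  null_idx <- which(tics <= eps)
  ds <- exclude_pixels(ds, null_idx, "null spectrum")
  ds <- log_step(ds, "exclude_null_spectra epsilon=%g excluded=%d", eps, length(null_idx))

  if (align && length(ds$spectra) > 1L) {
    ref <- class_average(ds$spectra)
    rc <- recalibrate(ds$spectra, ref, max_shift_ppm = max_shift_ppm)
    keep <- setdiff(seq_along(ds$spectra), rc$excluded$index)
    reasons <- rc$excluded$reason
    for (r in unique(reasons)) {
      ds_idx <- rc$excluded$index[reasons == r]
      ds$excluded <- rbind(ds$excluded,
                           data.frame(x = ds$coords$x[ds_idx],
                                      y = ds$coords$y[ds_idx], reason = r))
    }
    ds$spectra <- rc$spectra
    ds$coords <- ds$coords[keep, , drop = FALSE]
    rownames(ds$coords) <- NULL
    ds <- log_step(ds, "recalibrate max_shift_ppm=%g excluded=%d median_shift_ppm=%g",
                   max_shift_ppm, nrow(rc$excluded),
                   if (length(rc$shifts_ppm)) stats::median(rc$shifts_ppm) else NA)
  }

  ds$spectra <- lapply(ds$spectra, tic_normalize)
  ds <- log_step(ds, "tic_normalize")

  ds$spectra <- lapply(ds$spectra, function(s) {
    baseline_convex_hull(s, flatness = flatness)$spectrum
  })
  ds <- log_step(ds, "baseline_convex_hull flatness=%g", flatness)
  ds
}
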