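# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# AUC by explicit enumeration of all positive-negative pairs
brute_auc <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# lower convex hull by support lines: at each x, the hull equals the
# maximum over all point-pair chords that lie below every point
brute_lower_hull <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (j in 1:(n - 1)) {
    for (k in (j + 1):n) {
      slope <- (y[k] - y[j]) / (x[k] - x[j])
      line <- y[j] + slope * (x - x[j])
      if (all(line <= y + 1e-9)) base <- pmax(base, line)
    }
  }
  base
}

# modal c-value by exhaustive fine binning (bin width = coarse width / 10)
brute_modes <- function(v, bin_width) {
  fine <- bin_width / 10
  breaks <- seq(0, max(v) + fine, by = fine)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  mids <- breaks[-length(breaks)] + fine / 2
  mids[which.max(counts)]
}

# a small two-class slide spec used across tests: narrow mass range and a
# coarse axis keep the suite fast while preserving all planted structure
small_slide_spec <- function(seed = 1L, noise_sd = 1, ppm_jitter_sd = 200,
                             cv = 0.2, null_pixel_fraction = 0,
                             grid_shape = c(10L, 6L), ratio = 2) {
  slide_spec(grid_shape = grid_shape,
             planted_peaks = default_planted_peaks(ratio = ratio, cv = cv),
             mass_range = c(2000, 10000), mz_step = 4,
             noise_sd = noise_sd, ppm_jitter_sd = ppm_jitter_sd,
             null_pixel_fraction = null_pixel_fraction, seed = seed)
}
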