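#' Describe a planted spectral peak
#'
#' @param center_mz apex m/z in Da.
#' @param class_means named numeric vector, mean apex intensity per class
#'   label (arbitrary units, >= 0).
#' @param width peak FWHM in Da; defaults to constant resolving power
#'   `center_mz / resolving_power` (broad, smooth linear-TOF peaks).
#' @param cv relative intensity noise (fraction >= 0).
#' @param resolving_power m/z over FWHM used when `width` is missing.
#' @return an object of class `planted_peak`.
#' @export
planted_peak <- function(center_mz, class_means, width = center_mz / resolving_power,
                         cv = 0.2, resolving_power = 800) {
  assert_number(center_mz, "center_mz", lower = 1e-9)
  assert_number(width, "width", lower = 1e-12)
  assert_number(cv, "cv", lower = 0)
  if (is.null(names(class_means)) || any(class_means < 0)) {
    stopf("class_means must be a named vector of non-negative intensities")
  }
  structure(list(center_mz = center_mz, width = width,
                 class_means = class_means, cv = cv),
            class = "planted_peak")
}

# the paper's marker masses, planted with a diploid:aneuploid contrast
default_planted_peaks <- function(classes = c("diploid", "aneuploid"),
                                  ratio = 2, cv = 0.2) {
  centers <- c(2395, 3376, 4761, 4977, 6663, 8581)
  lapply(seq_along(centers), function(i) {
    up <- i %% 2 == 1   # alternate which class carries the higher mean
    m <- c(100, 100 * ratio)
    if (!up) m <- rev(m)
    names(m) <- classes
    planted_peak(centers[i], m, cv = cv)
  })
}

#' Specify a synthetic IMS slide
#'
#' Defines a rectangular acquisition grid split into labelled regions whose
#' pixels share class-specific planted-peak intensities, on top of a smooth
#' positive baseline, with ppm-scale calibration jitter, additive noise and
#' an optional fraction of near-zero ("null") pixels.
#'
#' @param grid_shape integer `c(columns, rows)`.
#' @param regions named list: class label -> integer matrix / data.frame of
#'   `(x, y)` pixel coordinates (0-based). `NULL` splits the grid into left
#'   and right halves labelled after the planted classes.
#' @param planted_peaks list of [planted_peak()]; default plants the six
#'   marker masses with a two-fold diploid/aneuploid contrast.
#' @param pixel_pitch micrometres (default 90).
#' @param mass_range `c(lo, hi)` Da (default 2000-25000).
#' @param mz_step sampling step of the common axis in Da.
#' @param baseline_amplitude scale of the decaying-exponential + sinusoid
#'   baseline (>= 0).
#' @param ppm_jitter_sd per-pixel multiplicative calibration error, ppm.
#' @param noise_sd additive intensity noise sd.
#' @param null_pixel_fraction fraction of pixels emitted with ~zero TIC.
#' @param seed RNG seed; identical spec + seed give bit-identical slides.
#' @return an object of class `slide_spec`.
#' @export
slide_spec <- function(grid_shape = c(20L, 10L), regions = NULL,
                       planted_peaks = default_planted_peaks(),
                       pixel_pitch = 90, mass_range = c(2000, 25000),
                       mz_step = 2, baseline_amplitude = 20,
                       ppm_jitter_sd = 200, noise_sd = 1,
                       null_pixel_fraction = 0, seed = 1L) {
  assert_number(null_pixel_fraction, "null_pixel_fraction", 0, 1 - 1e-12)
  assert_number(baseline_amplitude, "baseline_amplitude", lower = 0)
  assert_number(ppm_jitter_sd, "ppm_jitter_sd", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  classes <- unique(unlist(lapply(planted_peaks, function(p) names(p$class_means))))
  if (is.null(regions)) {
    half <- grid_shape[1] %/% 2
    grid <- expand.grid(x = 0:(grid_shape[1] - 1L), y = 0:(grid_shape[2] - 1L))
    regions <- list(as.matrix(grid[grid$x < half, ]),
                    as.matrix(grid[grid$x >= half, ]))
    names(regions) <- classes[1:2]
  }
  regions <- lapply(regions, function(r) {
    r <- as.matrix(r); storage.mode(r) <- "integer"; r
  })
  keys <- unlist(lapply(regions, function(r) paste(r[, 1], r[, 2])))
  if (anyDuplicated(keys)) stopf("region masks overlap")
  all_xy <- do.call(rbind, regions)
  if (any(all_xy < 0) || any(all_xy[, 1] >= grid_shape[1]) ||
      any(all_xy[, 2] >= grid_shape[2])) {
    stopf("region masks extend outside the %d x %d grid",
          grid_shape[1], grid_shape[2])
  }
  centers <- vapply(planted_peaks, `[[`, numeric(1), "center_mz")
  if (any(centers < mass_range[1]) || any(centers > mass_range[2])) {
    stopf("mass axis [%g, %g] does not cover all planted peaks",
          mass_range[1], mass_range[2])
  }
  structure(list(grid_shape = as.integer(grid_shape), regions = regions,
                 planted_peaks = planted_peaks, pixel_pitch = pixel_pitch,
                 mass_range = as.numeric(mass_range), mz_step = mz_step,
                 baseline_amplitude = baseline_amplitude,
                 ppm_jitter_sd = ppm_jitter_sd, noise_sd = noise_sd,
                 null_pixel_fraction = null_pixel_fraction,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# smooth positive baseline: decaying exponential + slow sinusoid + floor,
# so the convex-hull corrector has nontrivial curvature to remove
synth_baseline <- function(mz, amplitude, lo) {
  amplitude * (exp(-(mz - lo) / 4000) +
               0.25 * (1 + sin(2 * pi * (mz - lo) / 9000)) + 0.05)
}

#' Generate a synthetic IMS slide
#'
#' Emulates a linear-mode TOF acquisition: one profile spectrum per grid
#' pixel on a shared m/z axis, Gaussian peaks at the planted centers with
#' class-specific mean apex intensities, per-pixel multiplicative m/z
#' calibration jitter, additive noise, and a planted fraction of null
#' pixels with near-zero TIC.
#'
#' @param spec a [slide_spec()].
#' @return list with `dataset` (an [ims_dataset()]) and `truth` (data.frame
#'   `x`, `y`, `label`, `null` giving the planted region label per pixel).
#' @export
generate_ims_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  mz <- seq(spec$mass_range[1], spec$mass_range[2], by = spec$mz_step)
  base <- synth_baseline(mz, spec$baseline_amplitude, spec$mass_range[1])
  truth <- do.call(rbind, lapply(names(spec$regions), function(lab) {
    r <- spec$regions[[lab]]
    data.frame(x = r[, 1], y = r[, 2], label = lab)
  }))
  n_pix <- nrow(truth)
  with_seed(spec$seed, {
    truth$null <- as.logical(stats::rbinom(n_pix, 1, spec$null_pixel_fraction))
    spectra <- vector("list", n_pix)
    for (i in seq_len(n_pix)) {
      if (truth$null[i]) {
        y <- numeric(length(mz))
      } else {
        jitter <- 1 + stats::rnorm(1) * spec$ppm_jitter_sd * 1e-6
        y <- base
        for (p in spec$planted_peaks) {
          apex <- p$class_means[[truth$label[i]]]
          if (p$cv > 0) apex <- max(0, apex * (1 + p$cv * stats::rnorm(1)))
          sdv <- p$width / (2 * sqrt(2 * log(2)))
          y <- y + apex * exp(-((mz - p$center_mz * jitter)^2) / (2 * sdv^2))
        }
        if (spec$noise_sd > 0) {
          y <- pmax(0, y + stats::rnorm(length(mz)) * spec$noise_sd)
        }
      }
      spectra[[i]] <- ims_spectrum(mz, y, pixel = c(truth$x[i], truth$y[i]))
    }
  })
  ds <- ims_dataset(spectra, grid_shape = spec$grid_shape,
                    pixel_pitch = spec$pixel_pitch,
                    mass_range = spec$mass_range)
  ds <- log_step(ds, "generate_ims_slide seed=%d pixels=%d null_fraction=%g",
                 spec$seed, n_pix, spec$null_pixel_fraction)
  list(dataset = ds, truth = truth)
}

#' Specify a synthetic DNA-content histogram
#'
#' Per-nucleus DNA content (c-units; 2c = normal diploid) drawn from a
#' mixture of Gaussian stem lines, an optional scattered component above
#' 4.5c (aneuploid instability), and a remainder spread between the diploid
#' and tetraploid regions (proliferating S-phase population).
#'
#' @param stem_lines named-free list of `c(position, weight)` pairs, or a
#'   2-column matrix; positions in c-units (> 0), weights are fractions.
#' @param within_line_sd Gaussian sd of each stem line, c-units.
#' @param scatter_fraction_gt_4_5c planted fraction of nuclei above 4.5c.
#' @param n_cells number of nuclei (acquisition guideline >= 500).
#' @param seed RNG seed.
#' @return an object of class `histogram_spec`.
#' @export
histogram_spec <- function(stem_lines = list(c(2.0, 0.95)),
                           within_line_sd = 0.1,
                           scatter_fraction_gt_4_5c = 0,
                           n_cells = 1000L, seed = 1L) {
  sl <- do.call(rbind, lapply(stem_lines, function(p) p[1:2]))
  if (any(sl[, 1] <= 0)) stopf("stem-line c-positions must be > 0")
  assert_number(within_line_sd, "within_line_sd", lower = 1e-12)
  assert_number(scatter_fraction_gt_4_5c, "scatter_fraction_gt_4_5c", 0, 1)
  if (sum(sl[, 2]) + scatter_fraction_gt_4_5c > 1 + 1e-12) {
    stopf("stem-line weights plus scatter fraction exceed 1")
  }
  if (n_cells < 1) stopf("n_cells must be >= 1")
  structure(list(stem_lines = sl, within_line_sd = within_line_sd,
                 scatter_fraction_gt_4_5c = scatter_fraction_gt_4_5c,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "histogram_spec")
}

# Auer type implied by a spec's construction (expected fractions under the
# mixture, not a classification of any realized sample)
implied_auer_type <- function(spec) {
  sl <- spec$stem_lines
  sd <- spec$within_line_sd
  rem <- 1 - sum(sl[, 2]) - spec$scatter_fraction_gt_4_5c
  f_gt45 <- spec$scatter_fraction_gt_4_5c +
    sum(sl[, 2] * stats::pnorm(4.5, sl[, 1], sd, lower.tail = FALSE))
  mass_in <- function(lo, hi) {
    sum(sl[, 2] * (stats::pnorm(hi, sl[, 1], sd) - stats::pnorm(lo, sl[, 1], sd)))
  }
  f_dip <- mass_in(1.5, 2.5)
  f_tet <- mass_in(3.5, 4.5)
  # remainder and scatter both lie above 2.5c by construction
  f_gt25 <- sum(sl[, 2] * stats::pnorm(2.5, sl[, 1], sd, lower.tail = FALSE)) +
    rem + spec$scatter_fraction_gt_4_5c
  if (f_gt45 > 0.05) return("IV")
  if (any(sl[, 1] >= 3.5 & sl[, 1] <= 4.5) && f_dip + f_tet > 0.9) return("II")
  if (all(sl[, 1] >= 1.5 & sl[, 1] <= 2.5) && f_gt25 < 0.10) return("I")
  "III"
}

#' Generate a synthetic DNA-content histogram
#'
#' @param spec a [histogram_spec()].
#' @return list with `histogram` (a [dna_histogram()]) and `true_type`, the
#'   Auer type implied by the spec's construction (for recovery tests).
#' @export
generate_dna_histogram <- function(spec) {
  stopifnot(inherits(spec, "histogram_spec"))
  sl <- spec$stem_lines
  rem <- 1 - sum(sl[, 2]) - spec$scatter_fraction_gt_4_5c
  probs <- c(sl[, 2], spec$scatter_fraction_gt_4_5c, rem)
  with_seed(spec$seed, {
    comp <- sample.int(length(probs), spec$n_cells, replace = TRUE, prob = probs)
    vals <- numeric(spec$n_cells)
    for (k in seq_len(nrow(sl))) {
      idx <- comp == k
      vals[idx] <- stats::rnorm(sum(idx), sl[k, 1], spec$within_line_sd)
    }
    idx <- comp == nrow(sl) + 1L   # scattered instability component
    vals[idx] <- stats::runif(sum(idx), 4.6, 9.5)
    idx <- comp == nrow(sl) + 2L   # proliferating cells between the regions
    vals[idx] <- stats::runif(sum(idx), 2.55, 3.45)
    vals <- pmax(vals, 0.05)
  })
  list(histogram = dna_histogram(vals, source_id = sprintf("synthetic seed %d", spec$seed)),
       true_type = implied_auer_type(spec))
}

#' Specify a synthetic survival cohort
#'
#' Emulates the structure of a tumor immunohistochemistry cohort: per-group
#' immunopositivity on `[0, 1]` (logit-normal) and exponential overall
#' survival with a multiplicative hazard for marker-positive groups,
#' censored administratively.
#'
#' @param group_sizes named integer vector, group -> n.
#' @param ip_distributions named list, group -> `c(location, scale)`:
#'   `location` is the median immunopositivity, `scale` the logit-scale sd.
#' @param marker_positive character, names of groups carrying the hazard
#'   ratio.
#' @param hazard_ratio multiplicative hazard for marker-positive patients.
#' @param baseline_hazard events per month for marker-negative patients.
#' @param censor_time administrative censoring time, months.
#' @param seed RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(marker_neg = 200L, marker_pos = 200L),
                        ip_distributions = list(marker_neg = c(0.27, 0.8),
                                                marker_pos = c(0.55, 0.8)),
                        marker_positive = "marker_pos",
                        hazard_ratio = 13, baseline_hazard = 0.005,
                        censor_time = 174, seed = 1L) {
  if (any(group_sizes < 0)) stopf("group sizes must be >= 0")
  assert_number(hazard_ratio, "hazard_ratio", lower = 1e-12)
  assert_number(baseline_hazard, "baseline_hazard", lower = 1e-12)
  assert_number(censor_time, "censor_time", lower = 1e-12)
  structure(list(group_sizes = group_sizes,
                 ip_distributions = ip_distributions,
                 marker_positive = marker_positive,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_time = censor_time, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic survival cohort
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `id`, `group`, `marker` (logical),
#'   `survival_months`, `status` (`"dead"`/`"alive"`), `ip`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  marker <- groups %in% spec$marker_positive
  with_seed(spec$seed, {
    rate <- spec$baseline_hazard * ifelse(marker, spec$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    ip <- vapply(groups, function(g) {
      d <- spec$ip_distributions[[g]]
      stats::plogis(stats::rnorm(1, stats::qlogis(d[1]), d[2]))
    }, numeric(1))
  })
  dead <- t_event <= spec$censor_time
  data.frame(id = sprintf("S%03d", seq_len(n)), group = groups, marker = marker,
             survival_months = pmin(t_event, spec$censor_time),
             status = ifelse(dead, "dead", "alive"), ip = ip,
             row.names = NULL)
}
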