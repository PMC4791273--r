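make_gaussian <- function(center = 4977, apex = 100, fwhm = 8,
                          mz = seq(4800, 5200, by = 2), ramp = 0) {
  sdv <- fwhm / (2 * sqrt(2 * log(2)))
  ims_spectrum(mz, apex * exp(-(mz - center)^2 / (2 * sdv^2)) + ramp * (mz - mz[1]))
}

test_that("mass-range restriction keeps [lo, hi] and flags empty results", {
  s <- ims_spectrum(seq(1500, 30000, by = 100), rep(1, 286))
  r <- restrict_mass_range(s)
  expect_true(all(r$mz >= 2000 & r$mz <= 25000))
  expect_equal(length(r$mz), sum(s$mz >= 2000 & s$mz <= 25000))

  inside <- ims_spectrum(seq(3000, 4000, 10), runif(101))
  expect_equal(restrict_mass_range(inside)$intensity, inside$intensity)

  below <- ims_spectrum(seq(100, 1000, 100), rep(1, 10))
  expect_true(isTRUE(attr(restrict_mass_range(below), "null_spectrum")))
})

test_that("convex-hull baseline zeroes constant and linear spectra", {
  mz <- seq(2000, 3000, by = 10)
  flat <- baseline_convex_hull(ims_spectrum(mz, rep(7, length(mz))))
  expect_equal(flat$spectrum$intensity, rep(0, length(mz)))
  lin <- baseline_convex_hull(ims_spectrum(mz, 0.5 * mz - 100))
  expect_equal(lin$spectrum$intensity, rep(0, length(mz)), tolerance = 1e-12)
  expect_error(baseline_convex_hull(ims_spectrum(c(1, 2), c(1, 2))), ">= 3")
})

test_that("hull baseline matches the brute-force support-line oracle", {
  s <- make_gaussian(center = 5000, apex = 100, fwhm = 30, ramp = 0.05)
  out <- baseline_convex_hull(s, flatness = 1)  # pure hull, no smoothing
  oracle <- brute_lower_hull(s$mz, s$intensity)
  expect_equal(out$baseline$intensity, oracle, tolerance = 1e-8)
  # corrected apex recovers the planted 100 within 1%
  expect_lt(abs(max(out$spectrum$intensity) - 100) / 100, 0.01)
  # away from the peak the baseline tracks the ramp within 1%
  away <- s$mz < 4900 | s$mz > 5100
  ramp <- 0.05 * (s$mz - s$mz[1])
  expect_lt(max(abs(out$baseline$intensity[away] - ramp[away])) / max(ramp), 0.01)
})

test_that("baseline correction is non-negative and idempotent at the default flatness", {
  set.seed(31)
  for (i in 1:8) {
    mz <- seq(2000, 9000, by = 10)
    y <- 30 * exp(-(mz - 2000) / 2500) + 5 * (1 + sin(mz / 900)) +
      80 * exp(-(mz - sample(3000:8000, 1))^2 / 800) + abs(rnorm(length(mz)))
    once <- baseline_convex_hull(ims_spectrum(mz, y))$spectrum
    expect_true(all(once$intensity >= 0))
    twice <- baseline_convex_hull(once)$spectrum
    expect_equal(twice$intensity, once$intensity, tolerance = 1e-9)
  }
})

test_that("TIC normalization scales to unit sum and flags null spectra", {
  s <- ims_spectrum(c(100, 200), c(1, 3))
  expect_equal(tic_normalize(s)$intensity, c(0.25, 0.75))
  expect_equal(tic_normalize(tic_normalize(s))$intensity, c(0.25, 0.75))
  set.seed(32)
  r <- tic_normalize(ims_spectrum(1:50, runif(50)))
  expect_equal(sum(r$intensity), 1, tolerance = 1e-12)
  z <- tic_normalize(ims_spectrum(1:5, rep(0, 5)))
  expect_equal(attr(z, "exclude_reason"), "null spectrum")
  expect_error(tic_normalize(ims_spectrum(1:3, c(1, -1, 1))), "negative")
})

test_that("recalibration recovers planted ppm shifts and enforces the 1000 ppm cap", {
  mz <- seq(2000, 10000, by = 2)
  peaks <- c(2395, 3376, 4977, 6663, 8581)
  y <- rowSums(vapply(peaks, function(p) 120 * exp(-(mz - p)^2 / 50), numeric(length(mz))))
  ref <- ims_spectrum(mz, y + 1)

  same <- recalibrate(list(ref), ref)
  expect_equal(same$shifts_ppm, 0, tolerance = 1e-6)
  expect_equal(same$spectra[[1]]$intensity, ref$intensity, tolerance = 1e-9)

  shifted <- ims_spectrum(mz * (1 + 500e-6), ref$intensity)
  rec <- recalibrate(list(shifted), ref)
  expect_equal(nrow(rec$excluded), 0L)
  expect_lt(abs(rec$shifts_ppm - (-500)), 50)
  near_ref <- abs(ref$mz - 4977) < 40
  apex_ref <- ref$mz[near_ref][which.max(ref$intensity[near_ref])]
  aligned <- rec$spectra[[1]]
  near_ali <- abs(aligned$mz - 4977) < 40
  apex_ali <- aligned$mz[near_ali][which.max(aligned$intensity[near_ali])]
  expect_lt(abs(apex_ali - apex_ref), 0.5)

  far <- ims_spectrum(mz * (1 + 2000e-6), ref$intensity)
  rec2 <- recalibrate(list(far), ref)
  expect_equal(rec2$excluded$reason, "shift over limit")
  expect_length(rec2$spectra, 0L)
})

test_that("class averaging is the pointwise mean and concentrates with n", {
  s <- make_gaussian()
  expect_equal(class_average(list(s))$intensity, s$intensity)
  s3 <- ims_spectrum(s$mz, 3 * s$intensity)
  expect_equal(class_average(list(s, s3))$intensity, 2 * s$intensity)
  expect_error(class_average(list()), "empty")

  set.seed(33)
  noisy <- lapply(1:100, function(i) ims_spectrum(s$mz, s$intensity + rnorm(length(s$mz), sd = 2)))
  avg <- class_average(noisy)
  expect_true(all(abs(avg$intensity - s$intensity) < 3 * 2 / sqrt(100) * 3))
})

test_that("peak picking brackets apexes with flanking-minima windows", {
  s <- make_gaussian(center = 4977, apex = 50)
  w <- pick_peaks(s)
  expect_length(w, 1L)
  expect_true(w[[1]]$lo < 4977 && 4977 < w[[1]]$hi)
  expect_lt(abs(w[[1]]$center_mz - 4977), 2 + 1e-9)  # within one axis sample

  expect_length(pick_peaks(ims_spectrum(1:100, rep(1, 100))), 0L)

  mz <- seq(4000, 6000, by = 2)
  two <- ims_spectrum(mz, 60 * exp(-(mz - 4500)^2 / 40) + 90 * exp(-(mz - 5500)^2 / 40))
  ws <- pick_peaks(two)
  expect_length(ws, 2L)
  expect_true(ws[[1]]$hi <= ws[[2]]$lo)
  expect_true(ws[[1]]$lo < 4500 && 4500 < ws[[1]]$hi)
  expect_true(ws[[2]]$lo < 5500 && 5500 < ws[[2]]$hi)
})

test_that("end-point integration subtracts the chord and matches oracles", {
  mz <- seq(100, 200, by = 10)
  expect_equal(integrate_endpoint(ims_spectrum(mz, rep(5, 11)),
                                  peak_window(150, 100, 200)), 0)

  # isoceles triangle: apex h = 6, base b = 100 -> area h*b/2 = 300
  tri <- ims_spectrum(seq(0, 100, by = 10), c(0, 1.2, 2.4, 3.6, 4.8, 6, 4.8, 3.6, 2.4, 1.2, 0))
  expect_equal(integrate_endpoint(tri, peak_window(50, 0, 100)), 300)

  g <- make_gaussian(center = 5000, apex = 80, fwhm = 20,
                     mz = seq(4900, 5100, by = 4), ramp = 0.3)
  w <- peak_window(5000, 4940, 5060)
  got <- integrate_endpoint(g, w)
  # fine-grid rectangle-sum oracle on the same sampled signal
  fx <- seq(4940, 5060, by = 0.05)
  fy <- approx(g$mz, g$intensity, xout = fx)$y
  chord <- approx(c(4940, 5060), fy[c(1, length(fy))], xout = fx)$y
  oracle <- sum((fy - chord)) * 0.05
  expect_lt(abs(got - oracle) / oracle, 0.005)

  # affine additions across the window cancel out
  aff <- ims_spectrum(g$mz, g$intensity + 12 - 0.7 * g$mz)
  expect_equal(integrate_endpoint(aff, w), got, tolerance = 1e-9)

  expect_error(integrate_endpoint(g, peak_window(5000, 4000, 6000)), "outside")
})

test_that("peak matrices have one row per retained pixel and propagate exclusions", {
  out <- generate_ims_slide(small_slide_spec(seed = 41, null_pixel_fraction = 0.1))
  ds <- preprocess_ims(out$dataset)
  expect_equal(length(ds$spectra) + nrow(ds$excluded), prod(out$dataset$grid_shape))
  expect_true(all(ds$excluded$reason != ""))

  windows <- list(peak_window(2395, 2370, 2420), peak_window(4977, 4950, 5004))
  m <- build_peak_matrix(ds, windows)
  expect_equal(dim(m), c(length(ds$spectra), 2L))
  expect_true(all(m >= 0))
  excl_keys <- paste(ds$excluded$x, ds$excluded$y, sep = ",")
  expect_false(any(excl_keys %in% rownames(m)))
})

test_that("zero-noise slides give identical peak-area rows within a class", {
  out <- generate_ims_slide(small_slide_spec(seed = 42, noise_sd = 0,
                                             ppm_jitter_sd = 0, cv = 0))
  ds <- preprocess_ims(out$dataset, align = FALSE)
  windows <- list(peak_window(2395, 2370, 2420), peak_window(4977, 4950, 5004))
  m <- build_peak_matrix(ds, windows)
  lab <- out$truth$label[match(rownames(m), paste(out$truth$x, out$truth$y, sep = ","))]
  for (cl in unique(lab)) {
    rows <- m[lab == cl, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(col) diff(range(col)))), 0)
  }
})

test_that("the preprocessing log records every stage with its parameters", {
  out <- generate_ims_slide(small_slide_spec(seed = 43))
  ds <- preprocess_ims(out$dataset)
  expect_true(any(grepl("restrict_mass_range", ds$log)))
  expect_true(any(grepl("recalibrate", ds$log)))
  expect_true(any(grepl("tic_normalize", ds$log)))
  expect_true(any(grepl("baseline_convex_hull flatness=0.8", ds$log)))
})
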