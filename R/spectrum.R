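#' Construct a profile mass spectrum
#'
#' A spectrum is a pair of equal-length vectors: strictly increasing m/z
#' values (Da) and non-negative intensities, optionally tagged with the
#' pixel grid coordinate it was acquired at.
#'
#' @param mz numeric, strictly increasing m/z values in Da.
#' @param intensity numeric, same length as `mz`.
#' @param pixel optional integer vector `c(x, y)` grid coordinate.
#' @return an object of class `ims_spectrum`.
#' @export
ims_spectrum <- function(mz, intensity, pixel = NULL) {
  if (length(mz) != length(intensity)) {
    stopf("mz and intensity must have equal length (%d vs %d)",
          length(mz), length(intensity))
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stopf("mz must be strictly increasing")
  }
  if (!is.null(pixel)) {
    pixel <- as.integer(pixel[1:2])
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 pixel = pixel),
            class = "ims_spectrum")
}

#' @export
print.ims_spectrum <- function(x, ...) {
  cat(sprintf("<ims_spectrum> %d points, m/z %.1f-%.1f, TIC %.4g%s\n",
              length(x$mz),
              if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA,
              sum(x$intensity),
              if (is.null(x$pixel)) "" else sprintf(", pixel (%d,%d)", x$pixel[1], x$pixel[2])))
  invisible(x)
}

#' Total ion count of a spectrum
#' @param s an `ims_spectrum`.
#' @return sum of intensities.
#' @export
tic <- function(s) sum(s$intensity)

#' Construct an IMS dataset (one spectrum per retained grid pixel)
#'
#' @param spectra list of [ims_spectrum()] objects, each carrying a pixel.
#' @param grid_shape integer `c(columns, rows)` of the acquisition grid.
#' @param pixel_pitch lateral resolution in micrometres (default 90).
#' @param mass_range numeric `c(lo, hi)` observation range in Da.
#' @param excluded data.frame with columns `x`, `y`, `reason` for pixels
#'   dropped during acquisition or preprocessing.
#' @return an object of class `ims_dataset`.
#' @export
ims_dataset <- function(spectra, grid_shape, pixel_pitch = 90,
                        mass_range = c(2000, 25000),
                        excluded = data.frame(x = integer(), y = integer(),
                                              reason = character())) {
  assert_number(pixel_pitch, "pixel_pitch", lower = 1e-9)
  coords <- do.call(rbind, lapply(spectra, function(s) s$pixel))
  if (length(spectra) && (is.null(coords) || anyNA(coords))) {
    stopf("every spectrum in a dataset must carry a pixel coordinate")
  }
  coords <- as.data.frame(if (is.null(coords)) matrix(integer(), 0, 2) else coords)
  names(coords) <- c("x", "y")
  if (nrow(coords) && (any(coords < 0) ||
      any(coords$x >= grid_shape[1]) || any(coords$y >= grid_shape[2]))) {
    stopf("pixel coordinates must lie in [0, %d) x [0, %d)",
          grid_shape[1], grid_shape[2])
  }
  structure(list(spectra = spectra, coords = coords,
                 grid_shape = as.integer(grid_shape),
                 pixel_pitch = pixel_pitch,
                 mass_range = as.numeric(mass_range),
                 excluded = excluded,
                 log = character()),
            class = "ims_dataset")
}

#' @export
print.ims_dataset <- function(x, ...) {
  cat(sprintf("<ims_dataset> %d x %d grid @ %g um, %d retained / %d excluded spectra, m/z %g-%g\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_pitch,
              length(x$spectra), nrow(x$excluded),
              x$mass_range[1], x$mass_range[2]))
  if (length(x$log)) cat("  log:", length(x$log), "processing steps\n")
  invisible(x)
}

# append one machine-readable processing-log line
log_step <- function(ds, fmt, ...) {
  ds$log <- c(ds$log, sprintf(fmt, ...))
  ds
}

# move pixels to the excluded table, dropping their spectra
exclude_pixels <- function(ds, idx, reason) {
  if (!length(idx)) return(ds)
  ds$excluded <- rbind(ds$excluded,
                       data.frame(x = ds$coords$x[idx], y = ds$coords$y[idx],
                                  reason = reason))
  ds$spectra <- ds$spectra[-idx]
  ds$coords <- ds$coords[-idx, , drop = FALSE]
  rownames(ds$coords) <- NULL
  ds
}

#' Define a peak integration window
#'
#' @param center_mz apex position in Da.
#' @param lo,hi window bounds in Da, `lo < center_mz < hi`.
#' @param label window label; defaults to the apex rounded to whole Da.
#' @return an object of class `peak_window`.
#' @export
peak_window <- function(center_mz, lo, hi, label = sprintf("mz_%.0f", center_mz)) {
  if (!(lo < center_mz && center_mz < hi)) {
    stopf("need lo < center_mz < hi (got %g, %g, %g)", lo, center_mz, hi)
  }
  structure(list(center_mz = center_mz, lo = lo, hi = hi, label = label),
            class = "peak_window")
}

#' Write / read per-pixel spectra as TSV
#'
#' Long format with columns `x`, `y`, `mz`, `intensity` — the plain-text
#' interchange format for slides.
#'
#' @param ds an `ims_dataset`.
#' @param path file path.
#' @return `write_ims_tsv` returns `path` invisibly; `read_ims_tsv` an
#'   `ims_dataset`.
#' @export
write_ims_tsv <- function(ds, path) {
  tabs <- lapply(ds$spectra, function(s) {
    data.frame(x = s$pixel[1], y = s$pixel[2], mz = s$mz, intensity = s$intensity)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ims_tsv
#' @param pixel_pitch,mass_range dataset metadata (not stored in the TSV).
#' @export
read_ims_tsv <- function(path, pixel_pitch = 90, mass_range = c(2000, 25000)) {
  tab <- utils::read.delim(path)
  keys <- split(seq_len(nrow(tab)), paste(tab$x, tab$y))
  spectra <- lapply(keys, function(i) {
    i <- i[order(tab$mz[i])]
    ims_spectrum(tab$mz[i], tab$intensity[i], pixel = c(tab$x[i][1], tab$y[i][1]))
  })
  names(spectra) <- NULL
  ims_dataset(spectra,
              grid_shape = c(max(tab$x) + 1L, max(tab$y) + 1L),
              pixel_pitch = pixel_pitch, mass_range = mass_range)
}
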