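#' TopHat morphological baseline subtraction
#'
#' Subtracts the morphological opening (erosion then dilation with a flat
#' structuring element of the given width in Da) from the spectrum. The
#' opening is a lower envelope, so the output is non-negative and never
#' exceeds the input; features narrower than the window survive unchanged.
#'
#' @param spectrum An [msi_spectrum].
#' @param window Structuring-element width in Da (default 5; must exceed the
#'   grid spacing).
#' @return Baseline-subtracted [msi_spectrum].
#' @export
tophat_baseline <- function(spectrum, window = 5) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  dx <- stats::median(diff(spectrum$mz))
  if (window <= 0) stop("TopHat window must be > 0", call. = FALSE)
  if (window <= dx) stop("TopHat window must exceed the grid spacing", call. = FALSE)
  w <- .tophat_bins(window, dx)
  msi_spectrum(spectrum$mz, spectrum$intensity -
                 .opening(spectrum$intensity, w))
}

.tophat_bins <- function(window, dx) {
  w <- max(3L, as.integer(round(window / dx)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

.opening <- function(x, w) .running_max(.running_min(x, w), w)

#' Apply TopHat baseline subtraction to every pixel of a dataset
#' @param dataset An [msi_dataset].
#' @inheritParams tophat_baseline
#' @return The dataset with baseline-subtracted intensities.
#' @export
tophat_dataset <- function(dataset, window = 5) {
  dx <- stats::median(diff(dataset$mz))
  if (window <= dx) stop("TopHat window must exceed the grid spacing", call. = FALSE)
  w <- .tophat_bins(window, dx)
  for (i in seq_len(n_pixels(dataset))) {
    v <- dataset$intensities[i, ]
    dataset$intensities[i, ] <- v - .opening(v, w)
  }
  dataset
}

#' TIC-preserving resampling onto a new m/z axis
#'
#' Treats the spectrum as a histogram of ion counts on bins delimited by the
#' midpoints of the m/z axis and redistributes mass onto the destination bins
#' in proportion to bin overlap (area-weighted rebinning, implemented through
#' linear interpolation of the cumulative mass function). Total ion current
#' is conserved to floating-point accuracy when the new axis covers the old.
#'
#' @param spectrum An [msi_spectrum].
#' @param new_axis Strictly increasing destination axis covering the old axis.
#' @return Resampled [msi_spectrum] on `new_axis`.
#' @export
resample_tic_preserving <- function(spectrum, new_axis) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  new_axis <- as.numeric(new_axis)
  if (is.unsorted(new_axis, strictly = TRUE)) {
    stop("destination axis must be strictly increasing", call. = FALSE)
  }
  old_edges <- .bin_edges(spectrum$mz)
  new_edges <- .bin_edges(new_axis)
  # cumulative mass at old bin edges; piecewise-linear inside each bin
  cum <- c(0, cumsum(spectrum$intensity))
  at <- stats::approx(old_edges, cum, xout = pmin(pmax(new_edges,
                                                       old_edges[1L]),
                                                  old_edges[length(old_edges)]),
                      method = "linear", ties = "ordered")$y
  msi_spectrum(new_axis, pmax(0, diff(at)))
}

.bin_edges <- function(axis) {
  n <- length(axis)
  if (n == 1L) return(c(axis - 0.5, axis + 0.5))
  mid <- (axis[-1L] + axis[-n]) / 2
  c(axis[1L] - (mid[1L] - axis[1L]), mid, axis[n] + (axis[n] - mid[n - 1L]))
}

#' Pick peaks from a baseline-subtracted spectrum
#'
#' Local maxima with signal-to-noise ratio at or above `snr_min` are kept.
#' Noise is estimated as 1.4826 times the median absolute deviation from a
#' running median, both in a sliding window of `noise_window` bins; signal is
#' the apex height above the running median, which makes detection invariant
#' to uniform intensity scaling and insensitive to any residual pedestal left
#' by baseline subtraction. Peak centroids are
#' intensity-weighted means over the samples above half the apex height.
#' Adjacent equal-height maxima (plateaus) yield the lower-m/z sample.
#'
#' @param spectrum An [msi_spectrum] (baseline already subtracted).
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @param noise_window Sliding-window width in bins for the noise estimate
#'   (odd; default 101).
#' @return A `peak_list`: data.frame with columns `mz` (centroid), `intensity`
#'   (apex height) and `snr`.
#' @export
pick_peaks <- function(spectrum, snr_min = 3, noise_window = 101L) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  x <- spectrum$intensity
  n <- length(x)
  if (n < 3L || all(x == 0)) return(empty_peak_list())
  w <- min(as.integer(noise_window), if (n %% 2L) n else n - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  w <- max(w, 3L)
  med <- stats::runmed(x, w, endrule = "constant")
  noise <- 1.4826 * stats::runmed(abs(x - med), w, endrule = "constant")
  # left-strict, right-weak comparison keeps the lower-m/z sample of a plateau
  apex <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(apex)) return(empty_peak_list())
  # signal measured above the running median: the morphological opening is a
  # lower envelope, so residual noise rides on a positive pedestal that must
  # not count as signal
  sig <- x[apex] - med[apex]
  # scale-invariant noise floor: keeps float-level ripple on noiseless
  # Gaussian tails from acquiring infinite SNR, while true noiseless peaks
  # still score ~1e9
  floor_ <- 1e-9 * max(x)
  snr <- sig / pmax(noise[apex], floor_)
  apex <- apex[snr >= snr_min]
  snr <- snr[snr >= snr_min]
  if (!length(apex)) return(empty_peak_list())
  cent <- vapply(apex, function(i) .fwhm_centroid(spectrum$mz, x, i), numeric(1))
  o <- order(cent)
  peak_list(data.frame(mz = cent[o], intensity = x[apex][o], snr = snr[o]))
}

# intensity-weighted centroid over contiguous samples >= half apex height
.fwhm_centroid <- function(mz, x, i) {
  half <- x[i] / 2
  lo <- i; while (lo > 1L && x[lo - 1L] >= half && x[lo - 1L] <= x[lo]) lo <- lo - 1L
  hi <- i; while (hi < length(x) && x[hi + 1L] >= half && x[hi + 1L] <= x[hi]) hi <- hi + 1L
  idx <- lo:hi
  sum(mz[idx] * x[idx]) / sum(x[idx])
}

peak_list <- function(df) {
  stopifnot(all(c("mz", "intensity", "snr") %in% names(df)))
  structure(df, class = c("peak_list", "data.frame"))
}

empty_peak_list <- function() {
  peak_list(data.frame(mz = numeric(0), intensity = numeric(0),
                       snr = numeric(0)))
}

#' Fit an external quadratic mass calibration
#'
#' Least-squares quadratic mapping observed m/z to reference m/z, the
#' calibration model used with caesium iodide cluster calibrants. Matching:
#' if `observed` and `reference` have equal length they are taken as pairs;
#' otherwise each reference is matched to the nearest observed value within
#' `match_tol` Da. The fit is performed on a centred/scaled predictor for
#' conditioning and reported as raw coefficients.
#'
#' @param observed Observed m/z values (e.g. picked calibrant peaks).
#' @param reference Reference m/z values; defaults to [csi_reference_masses].
#' @param match_tol Pair-matching tolerance in Da (default 0.5).
#' @return An `mz_calibration` model with fields `coefficients` (c0, c1, c2
#'   such that calibrated = c0 + c1 x + c2 x^2), `residuals`, `rms`, and the
#'   matched pairs. Supports `predict()` and `print()`.
#' @export
fit_quadratic_calibration <- function(observed,
                                      reference = csi_reference_masses(),
                                      match_tol = 0.5) {
  if (length(observed) != length(reference)) {
    idx <- vapply(reference, function(r) {
      d <- abs(observed - r)
      i <- which.min(d)
      if (d[i] <= match_tol) i else NA_integer_
    }, integer(1))
    keep <- !is.na(idx)
    obs <- observed[idx[keep]]
    ref <- reference[keep]
  } else {
    obs <- as.numeric(observed)
    ref <- as.numeric(reference)
  }
  if (length(obs) < 3L) {
    stop("quadratic calibration needs at least 3 matched reference pairs",
         call. = FALSE)
  }
  mu <- mean(obs); sc <- stats::sd(obs)
  z <- (obs - mu) / sc
  fit <- stats::lm.fit(cbind(1, z, z^2), ref)
  b <- fit$coefficients
  # expand (b0 + b1 z + b2 z^2) back to raw-x coefficients
  c2 <- b[3L] / sc^2
  c1 <- b[2L] / sc - 2 * b[3L] * mu / sc^2
  c0 <- b[1L] - b[2L] * mu / sc + b[3L] * mu^2 / sc^2
  coefs <- stats::setNames(c(c0, c1, c2), c("c0", "c1", "c2"))
  res <- ref - (c0 + c1 * obs + c2 * obs^2)
  structure(list(coefficients = coefs, residuals = res,
                 rms = sqrt(mean(res^2)), observed = obs, reference = ref),
            class = "mz_calibration")
}

#' @export
print.mz_calibration <- function(x, ...) {
  cat(sprintf(paste0("<mz_calibration> calibrated = %.6g + %.8g*mz + %.3g*mz^2\n",
                     "  %d reference pairs, residual RMS %.3g Da\n"),
              x$coefficients[1L], x$coefficients[2L], x$coefficients[3L],
              length(x$residuals), x$rms))
  invisible(x)
}

#' Apply a quadratic calibration to m/z values
#' @param object An `mz_calibration`.
#' @param mz Numeric m/z values (or an [msi_spectrum], whose axis is mapped).
#' @param ... Unused.
#' @return Calibrated m/z values (or spectrum).
#' @export
predict.mz_calibration <- function(object, mz, ...) {
  cf <- object$coefficients
  if (inherits(mz, "msi_spectrum")) {
    return(msi_spectrum(cf[1L] + cf[2L] * mz$mz + cf[3L] * mz$mz^2,
                        mz$intensity))
  }
  cf[[1L]] + cf[[2L]] * mz + cf[[3L]] * mz^2
}

#' Run the spectral preprocessing chain over a dataset
#'
#' TopHat baseline subtraction, optional TIC-preserving resampling onto a
#' coarser axis, per-pixel peak picking, and optional quadratic calibration
#' of peak centroids.
#'
#' @param dataset An [msi_dataset].
#' @param tophat_window TopHat window in Da.
#' @param snr_min Peak-picking SNR threshold.
#' @param resample_to Optional destination axis for resampling (default:
#'   keep the acquisition axis).
#' @param calibration Optional `mz_calibration` applied to peak centroids.
#' @param noise_window Noise-estimation window in bins.
#' @return List with `dataset` (baseline-subtracted, possibly resampled) and
#'   `peaks` (one `peak_list` per pixel).
#' @export
preprocess_dataset <- function(dataset, tophat_window = 5, snr_min = 3,
                               resample_to = NULL, calibration = NULL,
                               noise_window = 101L) {
  dataset <- tophat_dataset(dataset, window = tophat_window)
  if (!is.null(resample_to)) {
    ints <- matrix(0, nrow = n_pixels(dataset), ncol = length(resample_to))
    for (i in seq_len(n_pixels(dataset))) {
      ints[i, ] <- resample_tic_preserving(get_spectrum(dataset, i),
                                           resample_to)$intensity
    }
    dataset <- msi_dataset(dataset$coords, resample_to, ints,
                           pitch_um = dataset$pitch_um,
                           metadata = dataset$metadata)
  }
  peaks <- lapply(seq_len(n_pixels(dataset)), function(i) {
    pl <- pick_peaks(get_spectrum(dataset, i), snr_min = snr_min,
                     noise_window = noise_window)
    if (!is.null(calibration) && nrow(pl)) pl$mz <- predict(calibration, pl$mz)
    pl
  })
  list(dataset = dataset, peaks = peaks)
}
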