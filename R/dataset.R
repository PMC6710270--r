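#' Construct a single mass spectrum
#'
#' @param mz Strictly increasing m/z axis in Da.
#' @param intensity Non-negative intensities, same length, no NaN.
#' @return An `msi_spectrum` (list with `mz`, `intensity`).
#' @export
msi_spectrum <- function(mz, intensity) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("m/z axis and intensities must have equal length", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) stop("spectrum contains NA/NaN", call. = FALSE)
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("m/z axis must be strictly increasing", call. = FALSE)
  }
  structure(list(mz = mz, intensity = intensity), class = "msi_spectrum")
}

#' @export
print.msi_spectrum <- function(x, ...) {
  cat(sprintf("<msi_spectrum> %d points, m/z %.3f-%.3f, TIC %.4g\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Construct an MSI dataset (continuous mode)
#'
#' A pixel grid with one spectrum per pixel, all sharing a common m/z axis.
#' Coordinates are 0-based integers (converted to imzML's 1-based convention
#' only at the file boundary).
#'
#' @param coords Integer matrix (n x 2) of 0-based `(x, y)` pixel coordinates;
#'   must be unique.
#' @param mz Common m/z axis (strictly increasing, Da).
#' @param intensities Numeric matrix, `n` pixels x `length(mz)` bins.
#' @param pitch_um Pixel pitch in micrometres (> 0).
#' @param metadata List; free-form acquisition metadata (polarity, mz_range).
#' @return An `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensities, pitch_um = 60,
                        metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 2L) stop("coords must be an n x 2 matrix", call. = FALSE)
  if (anyDuplicated(coords)) stop("duplicate pixel coordinates", call. = FALSE)
  if (any(coords < 0L)) stop("coordinates are 0-based and must be >= 0", call. = FALSE)
  if (!is.matrix(intensities)) intensities <- matrix(intensities, nrow = nrow(coords))
  if (nrow(intensities) != nrow(coords) || ncol(intensities) != length(mz)) {
    stop("intensities must be n_pixels x length(mz)", call. = FALSE)
  }
  if (pitch_um <= 0) stop("pixel pitch must be > 0", call. = FALSE)
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("common m/z axis must be strictly increasing", call. = FALSE)
  }
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, mz = as.numeric(mz),
                 intensities = intensities, pitch_um = pitch_um,
                 metadata = metadata),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf(paste0("<msi_dataset> %d pixels (%d x %d grid), pitch %g um\n",
                     "  m/z %.2f-%.2f (%d bins), total TIC %.4g\n"),
              n_pixels(x), max(x$coords[, "x"]) + 1L, max(x$coords[, "y"]) + 1L,
              x$pitch_um, min(x$mz), max(x$mz), length(x$mz),
              sum(x$intensities)))
  invisible(x)
}

#' Number of pixels in a dataset
#' @param dataset An `msi_dataset`.
#' @return Integer pixel count.
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

#' Per-pixel total ion current
#' @param dataset An `msi_dataset`.
#' @return Numeric vector of per-pixel TIC.
#' @export
tic <- function(dataset) rowSums(dataset$intensities)

#' Extract one pixel's spectrum
#' @param dataset An `msi_dataset`.
#' @param pixel Pixel index (1-based row of the coordinate table).
#' @return An [msi_spectrum].
#' @export
get_spectrum <- function(dataset, pixel) {
  msi_spectrum(dataset$mz, dataset$intensities[pixel, ])
}

# map an n-vector of per-pixel values onto the (y, x) image grid
pixel_image <- function(dataset, values, fill = NA_real_) {
  nx <- max(dataset$coords[, "x"]) + 1L
  ny <- max(dataset$coords[, "y"]) + 1L
  img <- matrix(fill, nrow = ny, ncol = nx)
  img[cbind(dataset$coords[, "y"] + 1L, dataset$coords[, "x"] + 1L)] <- values
  img
}
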