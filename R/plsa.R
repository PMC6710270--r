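#' Build a pixel-by-peak data cube from per-pixel peak lists
#'
#' Peak centroids are aggregated into m/z bins of `bin_width`; intensities
#' are summed per pixel and bin. Only occupied bins become columns.
#'
#' @param dataset An [msi_dataset] (supplies the pixel index).
#' @param peaklists List of `peak_list`s, one per pixel.
#' @param bin_width Bin width in Da (default 0.1).
#' @return An `msi_datacube`: list with `matrix` (pixels x bins, non-negative),
#'   `mz_bins` (bin centres), `coords`.
#' @export
build_datacube <- function(dataset, peaklists, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  stopifnot(length(peaklists) == n_pixels(dataset))
  pix <- rep.int(seq_along(peaklists),
                 vapply(peaklists, nrow, integer(1)))
  mz <- unlist(lapply(peaklists, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(peaklists, `[[`, "intensity"), use.names = FALSE)
  if (!length(mz)) stop("no peaks to build a data cube from", call. = FALSE)
  bin_idx <- as.integer(floor(mz / bin_width))
  bins <- sort(unique(bin_idx))
  col <- match(bin_idx, bins)
  m <- matrix(0, nrow = n_pixels(dataset), ncol = length(bins))
  for (k in seq_along(mz)) {
    m[pix[k], col[k]] <- m[pix[k], col[k]] + int[k]
  }
  structure(list(matrix = m, mz_bins = (bins + 0.5) * bin_width,
                 coords = dataset$coords),
            class = "msi_datacube")
}

#' @export
print.msi_datacube <- function(x, ...) {
  cat(sprintf("<msi_datacube> %d pixels x %d peak bins, total counts %.4g\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Fit a probabilistic latent semantic analysis (pLSA) model
#'
#' Decomposes the pixel-by-peak count matrix into `k` latent topics by
#' maximum-likelihood EM under the multinomial pLSA model: each pixel
#' (document) is a mixture over topics, each topic a distribution over peak
#' bins (words). Intensities are rounded to integer pseudo-counts. The
#' E-step computes posterior topic responsibilities per (pixel, peak); the
#' M-step re-estimates `P(topic|pixel)` and `P(peak|topic)`. The
#' log-likelihood is non-decreasing across iterations (an EM guarantee,
#' asserted at run time up to floating-point rounding). Multiple seeded
#' random restarts are run and the best likelihood kept; the fit is
#' deterministic for a fixed seed. All-zero pixels are excluded from fitting
#' and recorded.
#'
#' @param cube An `msi_datacube` (or a plain non-negative matrix).
#' @param k Number of topics (`1 <= k <= min(dim)`).
#' @param seed Integer seed.
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param n_restarts Random restarts (default 5).
#' @return A `plsa` model: `theta` (pixels x k, rows sum to 1), `phi`
#'   (k x bins, rows sum to 1), `loglik` (trace of the winning restart),
#'   `iterations`, `k`, `seed`, `dropped` (indices of all-zero pixels),
#'   `n_pixels`.
#' @export
plsa_fit <- function(cube, k, seed = 1L, max_iter = 500L, tol = 1e-6,
                     n_restarts = 5L) {
  V_full <- if (inherits(cube, "msi_datacube")) cube$matrix else as.matrix(cube)
  V_full <- round(V_full)
  if (any(V_full < 0)) stop("data cube must be non-negative", call. = FALSE)
  if (k < 1L || k > min(dim(V_full))) {
    stop("k must be between 1 and min(n_pixels, n_bins)", call. = FALSE)
  }
  dropped <- which(rowSums(V_full) == 0)
  keep <- setdiff(seq_len(nrow(V_full)), dropped)
  V <- V_full[keep, , drop = FALSE]
  n <- nrow(V); m <- ncol(V)
  nz <- which(V > 0)
  vnz <- V[nz]

  # EM with collapsed responsibilities: R = V / (theta phi) on the support;
  # both M-step updates must use the *old* theta/phi for the monotonicity
  # guarantee to hold
  run_em <- function(rseed) {
    set.seed(rseed)
    theta <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    theta <- theta / rowSums(theta)
    phi <- matrix(stats::runif(k * m, 0.1, 1), k, m)
    phi <- phi / rowSums(phi)
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      S <- theta %*% phi
      ll <- sum(vnz * log(S[nz]))
      ll_trace <- c(ll_trace, ll)
      if (ll < ll_prev - 1e-9 * abs(ll_prev)) {
        stop("internal error: EM log-likelihood decreased", call. = FALSE)
      }
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) <= tol * abs(ll_prev)) break
      ll_prev <- ll
      R <- matrix(0, n, m)
      R[nz] <- vnz / S[nz]
      theta_new <- theta * (R %*% t(phi))
      phi_new <- phi * (t(theta) %*% R)
      theta <- theta_new / pmax(rowSums(theta_new), .Machine$double.xmin)
      phi <- phi_new / pmax(rowSums(phi_new), .Machine$double.xmin)
    }
    list(theta = theta, phi = phi, loglik = ll_trace,
         iterations = length(ll_trace))
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- run_em(seed + r - 1L)
    if (is.null(best) || max(fit$loglik) > max(best$loglik)) best <- fit
  }
  theta_full <- matrix(NA_real_, nrow(V_full), k)
  theta_full[keep, ] <- best$theta
  structure(list(theta = theta_full, phi = best$phi, loglik = best$loglik,
                 iterations = best$iterations, k = k, seed = seed,
                 dropped = dropped, n_pixels = nrow(V_full),
                 mz_bins = if (inherits(cube, "msi_datacube")) cube$mz_bins,
                 coords = if (inherits(cube, "msi_datacube")) cube$coords),
            class = "plsa")
}

#' @export
print.plsa <- function(x, ...) {
  cat(sprintf(paste0("<plsa> k = %d topics, %d pixels (%d dropped as empty)\n",
                     "  converged after %d EM iterations, log-likelihood %.4f\n"),
              x$k, x$n_pixels, length(x$dropped), x$iterations,
              x$loglik[length(x$loglik)]))
  invisible(x)
}

#' @export
logLik.plsa <- function(object, ...) {
  structure(object$loglik[length(object$loglik)],
            df = (object$n_pixels - length(object$dropped)) * (object$k - 1) +
              object$k * (ncol(object$phi) - 1),
            class = "logLik")
}

#' Label pixels by their dominant pLSA topic
#'
#' Per-pixel argmax of `P(topic|pixel)`; ties break toward the lowest topic
#' index. Topic ids are 0-based (`0..k-1`); pixels dropped from fitting
#' (zero TIC) are labelled `-1` (background).
#'
#' @param model A fitted `plsa` model.
#' @return Integer vector of labels, one per pixel.
#' @export
label_pixels <- function(model) {
  stopifnot(inherits(model, "plsa"))
  lab <- rep(-1L, model$n_pixels)
  fitted_rows <- which(!is.na(model$theta[, 1L]))
  lab[fitted_rows] <- max.col(model$theta[fitted_rows, , drop = FALSE],
                              ties.method = "first") - 1L
  lab
}

#' Sum spectra over a region of interest
#'
#' @param dataset An [msi_dataset].
#' @param labels Integer label per pixel (as from [label_pixels], or ground
#'   truth labels).
#' @param region Label value selecting the region.
#' @return The element-wise sum of the region's spectra as an [msi_spectrum].
#' @export
roi_summed_spectrum <- function(dataset, labels, region) {
  stopifnot(length(labels) == n_pixels(dataset))
  idx <- which(labels == region)
  if (!length(idx)) stop("region ", region, " contains no pixels", call. = FALSE)
  msi_spectrum(dataset$mz, colSums(dataset$intensities[idx, , drop = FALSE]))
}
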