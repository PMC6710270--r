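#' Ion intensity image for an m/z window
#'
#' Per-pixel sum of intensity within `[mz - tol, mz + tol]`, arranged on the
#' pixel grid.
#'
#' @param dataset An [msi_dataset].
#' @param mz Window centre in Da.
#' @param tol Half-width in Da (> 0).
#' @return An `ion_image`: matrix (grid rows x cols) with attributes `mz`,
#'   `tol`.
#' @export
ion_image <- function(dataset, mz, tol) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  rng <- range(dataset$mz)
  if (mz + tol < rng[1L] || mz - tol > rng[2L]) {
    stop(sprintf("window %.4f +/- %.4f lies outside the acquisition range %.2f-%.2f",
                 mz, tol, rng[1L], rng[2L]), call. = FALSE)
  }
  cols <- which(dataset$mz >= mz - tol & dataset$mz <= mz + tol)
  vals <- rowSums(dataset$intensities[, cols, drop = FALSE])
  structure(pixel_image(dataset, vals, fill = 0), mz = mz, tol = tol,
            class = c("ion_image", "matrix", "array"))
}

#' Pearson spatial correlation between two ion images
#'
#' @param a,b `ion_image`s (or plain matrices) of identical shape.
#' @return Pearson correlation over pixels, in `[-1, 1]`. A zero-variance
#'   image is an error, not a silent 0.
#' @export
spatial_correlation <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have identical shape", call. = FALSE)
  va <- as.vector(a); vb <- as.vector(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("spatial correlation undefined for a zero-variance image", call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Group co-localised candidates by spatial correlation
#'
#' Builds the graph whose edges connect candidate ion images with Pearson
#' correlation at least `r_min` and takes connected components
#' (single-linkage grouping). Groups are numbered by their lightest member
#' m/z, so the result is independent of candidate input order.
#'
#' @param candidates A `br_candidates` table.
#' @param dataset The [msi_dataset] the candidates came from.
#' @param r_min Correlation threshold (default 0.7).
#' @param tol Ion-image window half-width in Da (default 0.05).
#' @return Integer group id per candidate (1-based), plus the pairwise
#'   correlation matrix as attribute `r`.
#' @export
colocalization_groups <- function(candidates, dataset, r_min = 0.7,
                                  tol = 0.05) {
  n <- nrow(candidates)
  if (n == 0L) return(integer(0))
  imgs <- lapply(candidates$mono_mz, function(m) ion_image(dataset, m, tol))
  r <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r[i, j] <- r[j, i] <- spatial_correlation(imgs[[i]], imgs[[j]])
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(r >= r_min, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by their lightest member m/z
  first_mz <- vapply(unique(comp), function(c) {
    min(candidates$mono_mz[comp == c])
  }, numeric(1))
  remap <- match(comp, unique(comp)[order(first_mz)])
  structure(remap, r = r)
}
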