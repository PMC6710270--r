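.gut_region_names <- c("lumen", "stratified_squamous_epithelium", "mucosa",
                       "muscularis_mucosae", "sub_mucosa", "muscularis")

#' Generate a tissue phantom label map
#'
#' Layout `"gut-bands"` builds concentric elliptical bands approximating a
#' gut cross-section: lumen innermost, then epithelial and muscular layers
#' outward. Band boundaries get a seeded low-order angular wobble so the
#' regions are not perfectly circular. Layout `"blocks"` splits the grid into
#' vertical blocks (useful for minimal phantoms). Deterministic for a fixed
#' seed.
#'
#' @param rows,cols Grid dimensions (`rows * cols >= 4`).
#' @param layout `"gut-bands"` or `"blocks"`.
#' @param n_regions Number of regions (default 6, the gut layers).
#' @param seed Integer seed for the boundary wobble.
#' @return An `msi_phantom`: list with `labels` (rows x cols integer matrix,
#'   values `1..n_regions`), `region_names`, `layout`, `seed`.
#' @examples
#' ph <- make_phantom(32, 32, "gut-bands", seed = 1)
#' table(ph$labels)
#' @export
make_phantom <- function(rows, cols, layout = c("gut-bands", "blocks"),
                         n_regions = 6L, seed = 1L) {
  if (rows * cols < 4L) stop("phantom needs at least 4 pixels", call. = FALSE)
  if (n_regions < 2L) stop("phantom needs >= 2 regions", call. = FALSE)
  layout <- match.arg(layout)
  set.seed(seed)
  if (layout == "gut-bands") {
    cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
    y <- matrix(seq_len(rows), rows, cols)
    x <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    r <- sqrt(((x - cx) / (cols / 2))^2 + ((y - cy) / (rows / 2))^2)
    theta <- atan2(y - cy, x - cx)
    # seeded wobble: 3rd-order angular perturbation of the band radius
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.02, 0.06)
    r <- r * (1 + amp * sin(3 * theta + phase))
    edges <- seq(0.25, 0.95, length.out = n_regions - 1L)
    edges <- edges * (1 + stats::runif(n_regions - 1L, -0.02, 0.02))
    labels <- matrix(findInterval(r, edges) + 1L, rows, cols)
    labels[labels > n_regions] <- n_regions
  } else {
    cuts <- as.integer(round(seq(0, cols, length.out = n_regions + 1L)))
    labels <- matrix(0L, rows, cols)
    for (k in seq_len(n_regions)) {
      labels[, (cuts[k] + 1L):cuts[k + 1L]] <- k
    }
  }
  names <- if (n_regions == 6L && layout == "gut-bands") .gut_region_names
           else paste0("region_", seq_len(n_regions))
  structure(list(labels = labels, region_names = names, layout = layout,
                 seed = seed),
            class = "msi_phantom")
}

#' @export
print.msi_phantom <- function(x, ...) {
  cat(sprintf("<msi_phantom> %d x %d, layout '%s', %d regions\n",
              nrow(x$labels), ncol(x$labels), x$layout,
              length(x$region_names)))
  print(stats::setNames(as.vector(table(factor(x$labels,
                                               seq_along(x$region_names)))),
                        x$region_names))
  invisible(x)
}
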