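#' Write the candidate report: CSV plus per-candidate ion maps
#'
#' One CSV row per candidate (member peaks, number of Br, score, ROI,
#' de-replication status, annotation, co-localisation group) and one
#' grayscale PNG ion map per candidate. Images are min-max scaled to 8 bit
#' per image; the scaling bounds are recorded in the CSV so relative
#' intensities remain recoverable. No candidate is dropped: de-replicated
#' rows are written with their `removed` flag.
#'
#' @param candidates A `br_candidates` table.
#' @param annotations Annotation table from [annotate_candidates] (optional).
#' @param dataset The source [msi_dataset] (needed for ion maps; optional).
#' @param dir Output directory (created if missing).
#' @param groups Optional co-localisation group ids per candidate.
#' @param tol Ion-map window half-width in Da.
#' @return Path of the written CSV, invisibly.
#' @export
write_report <- function(candidates, annotations = NULL, dataset = NULL,
                         dir = ".", groups = NULL, tol = 0.05) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "br_candidates.csv")
  n <- nrow(candidates)
  tab <- data.frame(
    candidate = seq_len(n),
    peaks_mz = vapply(seq_len(n), function(i) {
      paste(sprintf("%.4f", candidate_member_mz(candidates[i, ])),
            collapse = ";")
    }, character(1)),
    n_br = candidates$n_br,
    score = candidates$score,
    roi = candidates$roi,
    removed = candidates$removed,
    annotation = rep(NA_character_, n),
    ppm = rep(NA_real_, n),
    ambiguous = rep(NA_character_, n),
    coloc_group = if (is.null(groups)) rep(NA_integer_, n) else groups,
    ion_map = rep(NA_character_, n),
    map_min = rep(NA_real_, n),
    map_max = rep(NA_real_, n)
  )
  if (!is.null(annotations) && nrow(annotations)) {
    j <- match(seq_len(n), annotations$candidate)
    tab$annotation <- annotations$name[j]
    tab$ppm <- annotations$ppm[j]
    tab$ambiguous <- annotations$ambiguous[j]
  }
  if (!is.null(dataset) && n > 0L) {
    for (i in seq_len(n)) {
      img <- ion_image(dataset, candidates$mono_mz[i], tol)
      fn <- sprintf("ion_map_%03d_mz%.4f.png", i, candidates$mono_mz[i])
      rng <- range(img)
      scaled <- if (diff(rng) > 0) (img - rng[1L]) / diff(rng)
                else matrix(0, nrow(img), ncol(img))
      png::writePNG(scaled, file.path(dir, fn))
      tab$ion_map[i] <- fn
      tab$map_min[i] <- rng[1L]
      tab$map_max[i] <- rng[2L]
    }
  }
  utils::write.csv(tab, csv, row.names = FALSE, na = "")
  invisible(csv)
}

#' Write an integer matrix as plain-text PGM (P2)
#'
#' Used for label maps; plain-text so the image diff-tools and version
#' control can read it.
#'
#' @param mat Integer matrix (labels or 0-255 gray levels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path) {
  m <- as.matrix(mat)
  m <- m - min(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)),
               sprintf("%d", max(m, 1))), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
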