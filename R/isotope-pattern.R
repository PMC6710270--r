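#' Construct an isotope pattern object
#'
#' @param mz Strictly increasing m/z values (Da).
#' @param abundance Relative abundances (sum to 1 minus any pruning loss).
#' @param charge Integer charge (0 for a neutral distribution).
#' @param adduct Adduct label or `NA` for a neutral molecule.
#' @param pruned Total abundance removed by pruning.
#' @return An `isotope_pattern`: data.frame with columns `mz`, `abundance`
#'   and attributes `charge`, `adduct`, `pruned`.
#' @export
isotope_pattern <- function(mz, abundance, charge = 0L, adduct = NA_character_,
                            pruned = 0) {
  stopifnot(length(mz) == length(abundance), all(abundance >= 0))
  o <- order(mz)
  mz <- mz[o]; abundance <- abundance[o]
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("isotope pattern m/z values must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(mz = mz, abundance = abundance),
            charge = as.integer(charge), adduct = adduct, pruned = pruned,
            class = c("isotope_pattern", "data.frame"))
}

#' @export
print.isotope_pattern <- function(x, ...) {
  adduct <- attr(x, "adduct")
  cat(sprintf("<isotope_pattern> %d peaks%s  (pruned %.2e)\n", nrow(x),
              if (is.na(adduct)) " (neutral)" else paste0("  ", adduct),
              attr(x, "pruned")))
  print(data.frame(mz = sprintf("%.5f", x$mz),
                   abundance = sprintf("%.5f", x$abundance)),
        row.names = FALSE)
  invisible(x)
}

# -- internal convolution machinery ------------------------------------------
# a pattern here is a plain list(mass=, ab=)

.pattern_convolve <- function(a, b, merge_tol, work_prune) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$ab, b$ab)
  p <- .pattern_merge(list(mass = as.vector(mass), ab = as.vector(ab)), merge_tol)
  # drop negligible working mass but remember how much was dropped
  keep <- p$ab >= work_prune * max(p$ab)
  list(mass = p$mass[keep], ab = p$ab[keep],
       lost = sum(p$ab[!keep]))
}

# merge isotopologues closer than merge_tol Da by abundance-weighted centroid
.pattern_merge <- function(p, merge_tol) {
  o <- order(p$mass)
  mass <- p$mass[o]; ab <- p$ab[o]
  if (length(mass) > 1L) {
    grp <- cumsum(c(1, diff(mass) >= merge_tol))
    tot <- as.vector(tapply(ab, grp, sum))
    wm <- as.vector(tapply(ab * mass, grp, sum)) / tot
    mass <- wm; ab <- tot
  }
  list(mass = mass, ab = ab)
}

# element^n distribution by binary exponentiation
.element_power <- function(element, n, merge_tol, work_prune) {
  e <- isotope_table(element)
  base <- list(mass = e$mass, ab = e$abundance)
  acc <- NULL
  lost <- 0
  while (n > 0L) {
    if (bitwAnd(n, 1L)) {
      if (is.null(acc)) acc <- base
      else {
        r <- .pattern_convolve(acc, base, merge_tol, work_prune)
        lost <- lost + r$lost
        acc <- r[c("mass", "ab")]
      }
    }
    n <- bitwShiftR(n, 1L)
    if (n > 0L) {
      r <- .pattern_convolve(base, base, merge_tol, work_prune)
      base <- r[c("mass", "ab")]
    }
  }
  c(acc, list(lost = lost))
}

#' Full isotopic distribution of a formula or adduct ion
#'
#' Computes the isotopologue envelope by iterated convolution of per-element
#' isotope distributions. Isotopologues closer than `merge_tol` Da are merged
#' by abundance-weighted centroid (TOF instruments cannot resolve isotopic
#' fine structure); peaks below `prune` relative abundance are dropped after
#' the bookkeeping that keeps the reported `pruned` loss honest, so the
#' retained abundances sum to 1 minus `pruned`.
#'
#' If `adduct` is given, the envelope is computed for the ion formula (the
#' adduct's atoms added or removed) and shifted by the electron mass; m/z
#' values are then ion m/z rather than neutral masses.
#'
#' @param counts Formula string or `element_counts`.
#' @param adduct Adduct label, `adduct_spec`, or `NULL` for the neutral
#'   molecule.
#' @param prune Relative-abundance pruning threshold in `[0, 0.01]`
#'   (default 1e-4).
#' @param merge_tol Centroid merge tolerance in Da (default 0.01).
#' @return An [isotope_pattern].
#' @examples
#' isotope_distribution("Br")          # the 50.69/49.31 doublet
#' isotope_distribution("C16H8Br2N2O2", "[M]+")
#' @export
isotope_distribution <- function(counts, adduct = NULL, prune = 1e-4,
                                 merge_tol = 0.01) {
  stopifnot(prune >= 0, prune <= 0.01)
  counts <- parse_formula_or_counts(counts)
  charge <- 0L
  shift <- 0
  label <- NA_character_
  if (!is.null(adduct)) {
    if (!inherits(adduct, "adduct_spec")) adduct <- adduct_spec(adduct)
    counts <- add_counts(counts, adduct$atoms)
    charge <- adduct$charge
    shift <- -charge * .electron_mass
    label <- adduct$label
  }
  if (!length(counts)) {
    stop("cannot compute an isotope distribution for an empty formula",
         call. = FALSE)
  }
  work_prune <- min(prune, 1e-6) / 10 + 1e-15
  acc <- NULL
  lost <- 0
  for (el in names(counts)) {
    p <- .element_power(el, counts[[el]], merge_tol, work_prune)
    lost <- lost + p$lost
    if (is.null(acc)) acc <- p[c("mass", "ab")]
    else {
      r <- .pattern_convolve(acc, p[c("mass", "ab")], merge_tol, work_prune)
      lost <- lost + r$lost
      acc <- r[c("mass", "ab")]
    }
  }
  # final prune relative to normalised abundance
  tot <- sum(acc$ab) + lost
  rel <- acc$ab / tot
  keep <- rel >= prune
  pruned <- lost / tot + sum(rel[!keep])
  mz <- (acc$mass[keep] + shift) / max(1L, abs(charge))
  isotope_pattern(mz, rel[keep], charge = charge, adduct = label,
                  pruned = pruned)
}
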