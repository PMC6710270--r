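#' @useDynLib bromsi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Embedded IUPAC/NIST isotope table. Masses in Da, fractional abundances.
# Abundances per element must sum to 1 (validated at load); masses strictly
# increasing per element. 79Br/81Br at 50.69%/49.31% -- the near 1:1 doublet
# that makes bromine a usable mass tracer in complex GI spectra.
.isotope_table <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785), abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.00335483507), abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088989), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491461956, 16.99913170, 17.9991610),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(mass = 30.97376163, abundance = 1),
  Br = list(mass = c(78.9183376, 80.9162906), abundance = c(0.5069, 0.4931)),
  Na = list(mass = 22.9897692809, abundance = 1),
  K  = list(mass = c(38.96370668, 39.96399848, 40.96182576),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Cs = list(mass = 132.905451933, abundance = 1),
  I  = list(mass = 126.904473, abundance = 1)
)

# Electron rest mass in Da; all singly charged ion m/z values include it.
.electron_mass <- 0.00054857990907

#' Isotope table used throughout the package
#'
#' Returns the embedded table of isotopic masses and abundances. Every mass
#' used anywhere in the package (monoisotopic masses, adduct deltas, CsI
#' calibrants, isotope envelopes) derives from this single table, so the
#' printed caesium iodide calibration references are reproduced to five
#' decimal places.
#'
#' @param element Optional element symbol; if given, only that element's
#'   entry is returned.
#' @return A named list with per-element `mass` and `abundance` vectors, or a
#'   single element's entry.
#' @examples
#' isotope_table("Br")
#' @export
isotope_table <- function(element = NULL) {
  if (is.null(element)) return(.isotope_table)
  if (!element %in% names(.isotope_table)) {
    stop("unknown element symbol: '", element, "'", call. = FALSE)
  }
  .isotope_table[[element]]
}

#' Electron rest mass in Da
#' @return Scalar mass in Da.
#' @export
electron_mass <- function() .electron_mass

# Most abundant isotope mass per element (the "monoisotopic" convention).
.principal_mass <- function(element) {
  e <- isotope_table(element)
  e$mass[which.max(e$abundance)]
}

.validate_isotope_table <- function() {
  for (el in names(.isotope_table)) {
    e <- .isotope_table[[el]]
    stopifnot(abs(sum(e$abundance) - 1) <= 1e-9,
              !is.unsorted(e$mass, strictly = TRUE))
  }
  invisible(TRUE)
}
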