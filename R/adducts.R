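# Supported positive-mode adducts. Each entry records the atoms gained (+) or
# lost (-) relative to the neutral molecule M and the charge; the electron
# mass for the +1 charge is always included in the delta, which is what makes
# the printed CsI calibrants come out to five decimal places.
.adduct_defs <- list(
  "[M]+"     = list(atoms = c(),                charge = +1L),
  "[M]+."    = list(atoms = c(),                charge = +1L),
  "[M-H]+"   = list(atoms = c(H = -1L),         charge = +1L),
  "[M+H]+"   = list(atoms = c(H = +1L),         charge = +1L),
  "[M+Na]+"  = list(atoms = c(Na = +1L),        charge = +1L),
  "[M+K]+"   = list(atoms = c(K = +1L),         charge = +1L),
  "[MH+Na]+" = list(atoms = c(H = +1L, Na = +1L), charge = +1L)
)

normalise_adduct_label <- function(label) {
  lab <- gsub("−", "-", label)  # unicode minus
  lab <- gsub(" ", "", lab)
  if (!lab %in% names(.adduct_defs)) {
    stop("unknown adduct '", label, "'; supported: ",
         paste(setdiff(names(.adduct_defs), "[M]+."), collapse = ", "),
         call. = FALSE)
  }
  lab
}

#' Adduct specification
#'
#' Describes how an ion is formed from the neutral molecule: which atoms are
#' gained or lost and the charge. The mass delta includes the electron mass.
#' Supported labels: `[M]+` (electron loss / radical cation), `[M-H]+`
#' (hydride abstraction, modelled as loss of one H atom plus one electron),
#' `[M+H]+`, `[M+Na]+`, `[M+K]+`, `[MH+Na]+`.
#'
#' @param label Adduct label.
#' @return An `adduct_spec` with fields `label`, `atoms`, `charge`, `delta`
#'   (mass delta in Da including electron mass).
#' @examples
#' adduct_spec("[M-H]+")
#' @export
adduct_spec <- function(label) {
  lab <- normalise_adduct_label(label)
  def <- .adduct_defs[[lab]]
  delta <- 0
  for (el in names(def$atoms)) {
    delta <- delta + def$atoms[[el]] * .principal_mass(el)
  }
  delta <- delta - def$charge * .electron_mass
  structure(list(label = lab, atoms = def$atoms, charge = def$charge,
                 delta = delta),
            class = "adduct_spec")
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat(sprintf("<adduct_spec> %s  delta = %+0.6f Da  charge = %+d\n",
              x$label, x$delta, x$charge))
  invisible(x)
}

#' Supported adduct labels
#' @return Character vector of labels.
#' @export
supported_adducts <- function() setdiff(names(.adduct_defs), "[M]+.")

#' m/z of an adduct ion
#'
#' Neutral monoisotopic mass plus the adduct delta (electron mass included),
#' divided by the absolute charge.
#'
#' @param counts Formula string or `element_counts`.
#' @param adduct Adduct label or `adduct_spec`.
#' @return m/z in Da.
#' @examples
#' ion_mz("C8H4BrNO2", "[M-H]+")  # 223.9342, the 6-bromoisatin cation
#' ion_mz("Cs", "[M]+")           # 132.90490, first CsI calibration reference
#' @export
ion_mz <- function(counts, adduct) {
  if (!inherits(adduct, "adduct_spec")) adduct <- adduct_spec(adduct)
  (monoisotopic_mass(counts) + adduct$delta) / abs(adduct$charge)
}

#' Caesium iodide cluster calibrant m/z
#'
#' m/z of the cluster cation \[Cs(n+1) I(n)\]+ used for external quadratic
#' calibration: `(n+1) * mass(Cs) + n * mass(I) - electron mass`.
#'
#' @param n Cluster index (>= 0); vectorised.
#' @return m/z in Da.
#' @examples
#' csi_cluster_mz(0:5)
#' @export
csi_cluster_mz <- function(n) {
  if (any(n < 0)) stop("cluster index n must be >= 0", call. = FALSE)
  n <- as.numeric(n)
  (n + 1) * .principal_mass("Cs") + n * .principal_mass("I") - .electron_mass
}

#' Default CsI calibration reference set
#' @param n_clusters Number of clusters (default 6, indices 0..5).
#' @return Numeric vector of reference m/z values.
#' @export
csi_reference_masses <- function(n_clusters = 6L) {
  csi_cluster_mz(seq_len(n_clusters) - 1L)
}
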