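#' Default lipid background mass list
#'
#' A fixed panel of ~40 lipid-like species spanning m/z 400-1100, grouped
#' into the classes resolved by TLC-MALDI of gut tissue (short-chain
#' lipids/fragments, glycerolipids, phospholipids, phosphocholines,
#' triacylglycerides), plus engineered di-brominated look-alike decoys: pairs
#' of co-eluting species ~1.998 Da apart at ~1:1 intensity, which is exactly
#' how low-abundance lipid pairs can mimic a di-Br envelope. Decoys are
#' flagged so downstream ground truth can score de-replication.
#'
#' Species with a molecular formula get their ion m/z and isotope envelope
#' from the formula; decoys are mass-only entries (single peak each).
#'
#' @return Data frame with columns `name`, `formula` (NA for mass-only
#'   entries), `adduct`, `mz` (ion m/z), `class`, `decoy`, `decoy_pair`.
#' @export
default_lipid_background <- function() {
  series <- function(class, prefix, n_range, h_offset, n_O, adduct) {
    do.call(rbind, lapply(n_range, function(n) {
      f <- sprintf("C%dH%dO%d", n, 2L * n + h_offset, n_O)
      data.frame(name = sprintf("%s(%d)", prefix, n), formula = f,
                 adduct = adduct, mz = ion_mz(f, adduct), class = class,
                 decoy = FALSE, decoy_pair = NA_integer_)
    }))
  }
  pseries <- function(class, prefix, n_range, h_offset, adduct) {
    do.call(rbind, lapply(n_range, function(n) {
      f <- sprintf("C%dH%dNO8P", n, 2L * n + h_offset)
      data.frame(name = sprintf("%s(%d)", prefix, n), formula = f,
                 adduct = adduct, mz = ion_mz(f, adduct), class = class,
                 decoy = FALSE, decoy_pair = NA_integer_)
    }))
  }
  lip <- rbind(
    series("SL/F", "FRAG", 25:32, -5L, 4L, "[M+H]+"),   # ~409-508
    series("GL", "DG", 33:40, -3L, 5L, "[M+H]+"),       # ~540-638
    pseries("PL", "PE", 37:42, -1L, "[M+H]+"),          # ~692-762
    pseries("PC", "PC", 40:45, 1L, "[M+H]+"),           # ~736-806
    series("TG", "TG", 51:58, -8L, 6L, "[M+Na]+")       # ~842-940
  )
  br_step <- diff(isotope_table("Br")$mass)              # 1.99795 Da
  decoy <- data.frame(
    name = c("decoy_a_mono", "decoy_a_partner",
             "decoy_b_mono", "decoy_b_partner"),
    formula = NA_character_,
    adduct = NA_character_,
    mz = c(612.3000, 612.3000 + br_step, 744.4800, 744.4800 + br_step),
    class = "GL",
    decoy = TRUE,
    decoy_pair = c(1L, 1L, 2L, 2L))
  out <- rbind(lip, decoy)
  stopifnot(all(out$mz >= 400), all(out$mz <= 1100))
  rownames(out) <- NULL
  out
}

# isotope envelope (mz, abundance) for one lipid table row; mass-only entries
# contribute a single peak
.species_envelope <- function(row, prune = 1e-3, n_max = 4L) {
  if (is.na(row$formula)) {
    return(data.frame(mz = row$mz, abundance = 1))
  }
  p <- isotope_distribution(row$formula, row$adduct, prune = prune)
  utils::head(data.frame(mz = p$mz, abundance = p$abundance), n_max)
}

#' Expand a lipid mass list with isotopologue masses
#'
#' Used by de-replication: a candidate peak matching any isotopologue of a
#' known lipid (not only its monoisotopic peak) counts as a lipid match.
#'
#' @param lipids Lipid table as from [default_lipid_background].
#' @param prune Envelope pruning threshold.
#' @return Numeric vector of lipid isotopologue m/z values.
#' @export
lipid_isotopologue_masses <- function(lipids, prune = 1e-3) {
  sort(unlist(lapply(seq_len(nrow(lipids)), function(i) {
    .species_envelope(lipids[i, ], prune = prune)$mz
  })))
}
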