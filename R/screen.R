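#' Mono-/di-bromine isotope signature template
#'
#' Expected peak spacings and relative abundances for an envelope containing
#' `n_br` bromine atoms (singly charged, other elements' isotopes ignored):
#' spacing is `mass(81Br) - mass(79Br) = 1.99795` Da per step, abundances
#' come from the binomial combination of the two Br isotopes computed by the
#' isotope engine.
#'
#' @param n_br Number of bromine atoms (1 or 2).
#' @return A `halogen_template`: list with `n_br`, `spacings` (Da offsets of
#'   each member from the monoisotopic peak), `abundances`, `charge`.
#' @export
halogen_template <- function(n_br) {
  if (!n_br %in% c(1L, 2L)) stop("n_br must be 1 or 2", call. = FALSE)
  p <- isotope_distribution(sprintf("Br%d", n_br))
  structure(list(n_br = as.integer(n_br),
                 spacings = p$mz - p$mz[1L],
                 abundances = p$abundance,
                 charge = 1L),
            class = "halogen_template")
}

#' Cosine similarity between an observed intensity vector and a template
#'
#' Normalised dot product of the unit-normalised vectors; scale invariant,
#' in `[0, 1]` for non-negative input, 1 iff the observed vector is
#' proportional to the template. A zero vector scores 0.
#'
#' @param observed Non-negative observed intensities.
#' @param template Template abundances (same length).
#' @return Score in `[0, 1]`.
#' @export
score_isotope_match <- function(observed, template) {
  stopifnot(length(observed) == length(template),
            all(observed >= 0), all(template >= 0))
  no <- sqrt(sum(observed^2)); nt <- sqrt(sum(template^2))
  if (no == 0 || nt == 0) return(0)
  min(1, sum(observed * template) / (no * nt))
}

#' Find mono- and di-brominated isotope signatures in a peak list
#'
#' For each peak, partners are searched at `+1.99795` Da (and `+3.99590` for
#' di-Br) within `tol_mz`; the member intensity vector is scored against the
#' Br template by cosine similarity and candidates scoring at least
#' `score_min` are kept. A peak may belong to at most one candidate: di-Br
#' assignments claim their peaks before mono-Br (then by score), so a clean
#' Br2 triplet never also yields its Br1 sub-pairs.
#'
#' @param peaks A `peak_list` (centroided).
#' @param tol_mz Partner-matching tolerance in Da (default 0.05, TOF-scale).
#' @param score_min Minimum template cosine score (default 0.95).
#' @param roi Optional ROI label recorded on the candidates.
#' @return A `br_candidates` data.frame: one row per candidate with columns
#'   `mono_mz`, `n_br`, `score`, `mz1..mz3`, `int1..int3`, `roi`, `removed`.
#' @export
find_halogen_signatures <- function(peaks, tol_mz = 0.05, score_min = 0.95,
                                    roi = NA_character_) {
  stopifnot(tol_mz > 0)
  mz <- peaks$mz; int <- peaks$intensity
  cand <- list()
  for (n_br in c(2L, 1L)) {
    tpl <- halogen_template(n_br)
    for (i in seq_along(mz)) {
      members <- i
      ok <- TRUE
      for (s in tpl$spacings[-1L]) {
        j <- which(abs(mz - (mz[i] + s)) <= tol_mz)
        if (!length(j)) { ok <- FALSE; break }
        members <- c(members, j[which.min(abs(mz[j] - (mz[i] + s)))])
      }
      if (!ok) next
      sc <- score_isotope_match(int[members], tpl$abundances)
      if (sc >= score_min) {
        cand[[length(cand) + 1L]] <- list(members = members, n_br = n_br,
                                          score = sc)
      }
    }
  }
  if (!length(cand)) return(empty_br_candidates())
  # overlap resolution: Br2 before Br1, then by score; each peak claimed once
  ord <- order(-vapply(cand, `[[`, integer(1), "n_br"),
               -vapply(cand, `[[`, numeric(1), "score"),
               vapply(cand, function(c) mz[c$members[1L]], numeric(1)))
  claimed <- logical(length(mz))
  rows <- list()
  for (c in cand[ord]) {
    if (any(claimed[c$members])) next
    claimed[c$members] <- TRUE
    mzv <- intv <- rep(NA_real_, 3L)
    mzv[seq_along(c$members)] <- mz[c$members]
    intv[seq_along(c$members)] <- int[c$members]
    rows[[length(rows) + 1L]] <- data.frame(
      mono_mz = mz[c$members[1L]], n_br = c$n_br, score = c$score,
      mz1 = mzv[1L], mz2 = mzv[2L], mz3 = mzv[3L],
      int1 = intv[1L], int2 = intv[2L], int3 = intv[3L],
      roi = roi, removed = NA_character_)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mono_mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("br_candidates", "data.frame"))
}

empty_br_candidates <- function() {
  structure(data.frame(mono_mz = numeric(0), n_br = integer(0),
                       score = numeric(0), mz1 = numeric(0), mz2 = numeric(0),
                       mz3 = numeric(0), int1 = numeric(0), int2 = numeric(0),
                       int3 = numeric(0), roi = character(0),
                       removed = character(0)),
            class = c("br_candidates", "data.frame"))
}

candidate_member_mz <- function(cand_row) {
  v <- unlist(cand_row[c("mz1", "mz2", "mz3")], use.names = FALSE)
  v[!is.na(v)]
}

candidate_member_int <- function(cand_row) {
  v <- unlist(cand_row[c("int1", "int2", "int3")], use.names = FALSE)
  v[!is.na(v)]
}

#' De-replicate lipid look-alikes from Br candidates
#'
#' A candidate is flagged `removed = "lipid"` when either (a) every member
#' peak coincides within `tol_mz` with an isotopologue of a known lipid
#' species, or (b) a lipid whose monoisotopic ion m/z matches the candidate's
#' lightest peak has an isotope envelope that explains the observed
#' intensities better (higher cosine) than the Br template does. Nothing is
#' deleted; screening output and report keep the flagged rows.
#'
#' @param candidates A `br_candidates` table.
#' @param lipids Lipid table (as [default_lipid_background]) or a numeric
#'   vector of lipid m/z values; `NULL`/empty leaves candidates unchanged.
#' @param tol_mz Matching tolerance in Da (default 0.15 -- about half the peak
#'   FWHM at the top of the lipid range, deliberately wider
#'   than the partner-spacing tolerance, because overlapping lipid envelopes
#'   pull apparent centroids off the single-species position).
#' @return The candidate table with the `removed` column filled in.
#' @export
dereplicate_lipids <- function(candidates, lipids, tol_mz = 0.15) {
  if (is.null(lipids) || !NROW(lipids) || !nrow(candidates)) return(candidates)
  if (is.numeric(lipids)) {
    iso_mz <- sort(lipids)
    lipid_tab <- NULL
  } else {
    iso_mz <- lipid_isotopologue_masses(lipids)
    lipid_tab <- lipids
  }
  near <- function(x) any(abs(iso_mz - x) <= tol_mz)
  for (i in seq_len(nrow(candidates))) {
    mzs <- candidate_member_mz(candidates[i, ])
    ints <- candidate_member_int(candidates[i, ])
    all_lipid <- all(vapply(mzs, near, logical(1)))
    env_better <- FALSE
    if (!is.null(lipid_tab)) {
      hit <- which(abs(lipid_tab$mz - mzs[1L]) <= tol_mz &
                     !is.na(lipid_tab$formula))
      for (h in hit) {
        env <- .species_envelope(lipid_tab[h, ], n_max = length(mzs))
        obs_on_lipid <- vapply(env$mz, function(m) {
          j <- which(abs(mzs - m) <= tol_mz)
          if (length(j)) ints[j[1L]] else 0
        }, numeric(1))
        tpl <- halogen_template(candidates$n_br[i])
        if (score_isotope_match(obs_on_lipid, env$abundance) >
            score_isotope_match(ints, tpl$abundances)) {
          env_better <- TRUE
          break
        }
      }
    }
    if (all_lipid || env_better) candidates$removed[i] <- "lipid"
  }
  candidates
}

#' Retained (non-de-replicated) candidates
#' @param candidates A `br_candidates` table.
#' @return The subset with no `removed` flag.
#' @export
retained_candidates <- function(candidates) {
  candidates[is.na(candidates$removed), , drop = FALSE]
}
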