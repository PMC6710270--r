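#' Load a compound library
#'
#' The library CSV has columns `name`, `formula` (may be empty for mass-only
#' entries), `adducts` (semicolon-separated labels), `expected_mz`
#' (slash-separated printed m/z values, informational), `source`. The default
#' shipped library contains the mono- and di-brominated indoles of the
#' natural extract and the xenobiotic M-series metabolites.
#'
#' @param path CSV path; default is the library shipped with the package.
#' @return Data frame with class `compound_library`.
#' @export
read_compound_library <- function(path = system.file("extdata",
                                                     "compound_library.csv",
                                                     package = "bromsi")) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "adducts", "expected_mz", "source")
  missing <- setdiff(need, names(lib))
  if (length(missing)) {
    stop("compound library lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lib$formula[!nzchar(trimws(lib$formula))] <- NA_character_
  structure(lib, class = c("compound_library", "data.frame"))
}

#' Annotate Br candidates against a compound library
#'
#' Each candidate's lightest (monoisotopic) peak is matched against every
#' library formula x adduct combination within `tol_ppm`; mass-only library
#' entries are matched against their stated m/z. All matches are reported
#' ranked by absolute ppm error -- isobars (such as the dibromoindigo /
#' dibromoindirubin pair, identical formula) are listed together and never
#' silently collapsed to one identity. Candidates with no match are assigned
#' sequential `M1`, `M2`, ... placeholder names, the convention for
#' uncharacterised brominated metabolite series.
#'
#' @param candidates A `br_candidates` table.
#' @param library A `compound_library` (default: shipped library).
#' @param adducts Adduct labels to consider for formula entries (default
#'   [supported_adducts]).
#' @param tol_ppm Match tolerance in ppm (default 10 for exact-mass data;
#'   use ~200 for uncalibrated DIOS-grade data).
#' @return Data frame with one row per candidate: `candidate`, `mono_mz`,
#'   `name` (best match or placeholder), `adduct`, `ppm`, `ambiguous`
#'   (semicolon list of all matches within tolerance), `n_matches`.
#' @export
annotate_candidates <- function(candidates, library = read_compound_library(),
                                adducts = supported_adducts(), tol_ppm = 10) {
  theo <- .library_ions(library, adducts)
  placeholder <- 0L
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    m <- candidates$mono_mz[i]
    ppm <- (m - theo$mz) / theo$mz * 1e6
    hit <- which(abs(ppm) <= tol_ppm)
    if (length(hit)) {
      hit <- hit[order(abs(ppm[hit]))]
      data.frame(candidate = i, mono_mz = m,
                 name = theo$name[hit[1L]], adduct = theo$adduct[hit[1L]],
                 ppm = ppm[hit[1L]],
                 ambiguous = paste(sprintf("%s %s (%+.1f ppm)",
                                           theo$name[hit], theo$adduct[hit],
                                           ppm[hit]), collapse = "; "),
                 n_matches = length(hit))
    } else {
      data.frame(candidate = i, mono_mz = m, name = NA_character_,
                 adduct = NA_character_, ppm = NA_real_,
                 ambiguous = "", n_matches = 0L)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(candidate = integer(0), mono_mz = numeric(0),
                      name = character(0), adduct = character(0),
                      ppm = numeric(0), ambiguous = character(0),
                      n_matches = integer(0)))
  }
  unk <- which(is.na(out$name))
  if (length(unk)) {
    # continue the library's M-series numbering so placeholders never
    # collide with catalogued metabolite names
    used <- regmatches(library$name, regexpr("^M[0-9]+", library$name))
    start <- if (length(used)) max(as.integer(sub("M", "", used))) else 0L
    out$name[unk] <- paste0("M", start + seq_along(unk))
  }
  out
}

# expand the library into theoretical (name, adduct, mz) ion rows
.library_ions <- function(library, adducts) {
  rows <- lapply(seq_len(nrow(library)), function(i) {
    f <- library$formula[i]
    if (!is.na(f)) {
      labs <- trimws(strsplit(library$adducts[i], ";")[[1]])
      labs <- labs[nzchar(labs)]
      if (!length(labs)) labs <- adducts
      labs <- intersect(labs, adducts)
      if (!length(labs)) return(NULL)
      data.frame(name = library$name[i], adduct = labs,
                 mz = vapply(labs, function(a) ion_mz(f, a), numeric(1)))
    } else {
      mzs <- suppressWarnings(as.numeric(strsplit(
        as.character(library$expected_mz[i]), "/")[[1]]))
      mzs <- mzs[is.finite(mzs)]
      if (!length(mzs)) return(NULL)
      # mass-only entry: the first listed m/z is the monoisotopic target
      data.frame(name = library$name[i], adduct = "(as listed)",
                 mz = mzs[1L])
    }
  })
  do.call(rbind, rows)
}

#' Region fold change of a candidate signature
#'
#' Ratio of the candidate's TIC-normalised intensity between two ROI summed
#' spectra: `(I_b / TIC_b) / (I_a / TIC_a)`, where the candidate intensity is
#' the summed intensity over all member-peak windows. TIC normalisation makes
#' sections acquired separately comparable.
#'
#' @param spectrum_a,spectrum_b ROI summed spectra ([msi_spectrum]).
#' @param candidate One row of a `br_candidates` table.
#' @param tol Window half-width in Da (default 0.05).
#' @return Fold change of b relative to a.
#' @export
region_fold_change <- function(spectrum_a, spectrum_b, candidate, tol = 0.05) {
  stopifnot(inherits(spectrum_a, "msi_spectrum"),
            inherits(spectrum_b, "msi_spectrum"))
  mzs <- candidate_member_mz(candidate)
  win_sum <- function(sp) {
    sum(vapply(mzs, function(m) {
      sum(sp$intensity[sp$mz >= m - tol & sp$mz <= m + tol])
    }, numeric(1)))
  }
  ia <- win_sum(spectrum_a); ib <- win_sum(spectrum_b)
  if (ia == 0 && ib == 0) {
    stop("candidate signature absent from both regions", call. = FALSE)
  }
  ta <- sum(spectrum_a$intensity); tb <- sum(spectrum_b$intensity)
  if (ia == 0 || ta == 0 || tb == 0) {
    stop("zero denominator in fold-change computation", call. = FALSE)
  }
  (ib / tb) / (ia / ta)
}
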