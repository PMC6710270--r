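#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style formula strings such as `"C8H4BrNO2"`. Underscores used
#' as subscript markup (`"C_8_H_4_BrNO_2_"`) are tolerated and stripped.
#' Parenthesised groups are not part of the grammar.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts, in Hill order, with class
#'   `element_counts`.
#' @examples
#' parse_formula("C8H4BrNO2")
#' parse_formula("C16H8Br2N2O2")
#' @export
parse_formula <- function(text) {
  if (inherits(text, "element_counts")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("_", "", text)
  if (!nzchar(s)) return(element_counts(integer(0)))
  pos <- 1L
  n <- nchar(s)
  counts <- integer(0)
  while (pos <= n) {
    m <- regmatches(substr(s, pos, n),
                    regexec("^([A-Z][a-z]?)([0-9]*)", substr(s, pos, n)))[[1]]
    if (length(m) == 0L || !nzchar(m[2L])) {
      stop("cannot parse formula '", text, "' at '", substr(s, pos, n), "'",
           call. = FALSE)
    }
    sym <- m[2L]
    if (!sym %in% names(.isotope_table)) {
      # two-letter greediness can swallow the next element's lowercase; there
      # are no lowercase-second-letter symbols in our table that alias, so an
      # unknown symbol is a genuine user error
      stop("unknown element symbol '", sym, "' in formula '", text, "'",
           call. = FALSE)
    }
    cnt <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m[2L]) + nchar(m[3L])
  }
  element_counts(counts)
}

#' Construct an element-counts object
#'
#' @param counts Named non-negative integer vector (element symbol -> count).
#' @return An `element_counts` object in canonical Hill order.
#' @export
element_counts <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("counts must be a named vector", call. = FALSE)
    }
    unknown <- setdiff(names(counts), names(.isotope_table))
    if (length(unknown)) {
      stop("unknown element symbol '", unknown[1L], "'", call. = FALSE)
    }
    if (any(counts < 0)) stop("element counts must be >= 0", call. = FALSE)
    counts <- counts[hill_order(names(counts))]
  }
  structure(as.integer(stats::setNames(counts, names(counts))),
            names = names(counts), class = "element_counts")
}

# Hill convention: C first, H second, remaining elements alphabetical;
# if no carbon, everything alphabetical.
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    c(intersect(c("C", "H"), symbols), sort(setdiff(symbols, c("C", "H"))))
  } else {
    sort(symbols)
  }
}

#' Format element counts as a Hill-order formula string
#' @param counts An `element_counts` object or named vector.
#' @return Formula string, e.g. `"C8H4BrNO2"`.
#' @export
format_formula <- function(counts) {
  counts <- element_counts(counts)
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<element_counts> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

# counts arithmetic (used when an adduct adds/removes atoms)
add_counts <- function(a, b) {
  out <- stats::setNames(as.integer(a), names(a))
  for (el in names(b)) {
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + b[[el]]
  }
  if (any(out < 0)) stop("adduct removes atoms the formula does not contain",
                         call. = FALSE)
  element_counts(out)
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of the most-abundant-isotope mass of each atom (e.g. 12C, 1H, 79Br).
#' Additive over disjoint formula unions.
#'
#' @param counts Formula string or `element_counts`.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("C8H4BrNO2")   # 6-bromoisatin, 224.9425
#' monoisotopic_mass("C16H8Br2N2O2") # dibromoindigo/-indirubin, 417.8953
#' @export
monoisotopic_mass <- function(counts) {
  counts <- parse_formula_or_counts(counts)
  if (!length(counts)) return(0)
  sum(vapply(names(counts), .principal_mass, numeric(1)) * as.numeric(counts))
}

parse_formula_or_counts <- function(x) {
  if (inherits(x, "element_counts")) x else parse_formula(x)
}
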