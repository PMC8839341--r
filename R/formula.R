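# Elemental-formula arithmetic: the unit of all mass bookkeeping in the
# package. Formulas are named integer vectors (element symbol -> count),
# printed and parsed in Hill notation (C first, H second, then alphabetical).

# Monoisotopic atomic masses in Da, CODATA/IUPAC (AME2020 / CIAAW),
# most abundant isotope of each supported element.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268
)

#' Monoisotopic mass of water (Da)
#'
#' The mass of one H2O molecule, lost for every ester bond formed.
#' @export
water_mass <- function() {
  unname(2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]])
}

#' Parse a Hill-notation elemental formula
#'
#' Converts a formula string such as `"C26H28O8"` into a named integer
#' vector of element counts. Only neutral, isotope-free formulas are
#' supported; charge is handled by the adduct layer
#' (see [adduct_mz()]).
#'
#' @param text A single formula string. Supported elements:
#'   C, H, N, O, S, P, Na, K, Cl.
#' @return A named integer vector of class `"elemental_formula"` with one
#'   entry per element present (zero-count elements are dropped).
#' @examples
#' parse_formula("C8H6O4")   # phthalic acid
#' parse_formula("H2O")
#' @seealso [format_formula()], [monoisotopic_mass()], [combine_formulas()]
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  tokens <- stringr::str_match_all(text, "([A-Z][a-z]?)([0-9]*)")[[1]]
  tokens <- tokens[nzchar(tokens[, 1L]), , drop = FALSE]
  consumed <- paste0(tokens[, 1L], collapse = "")
  if (!identical(consumed, text)) {
    stop("malformed formula string: ", text, call. = FALSE)
  }
  elements <- tokens[, 2L]
  unknown <- setdiff(elements, names(.ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- ifelse(nzchar(tokens[, 3L]), suppressWarnings(as.integer(tokens[, 3L])), 1L)
  if (anyNA(counts)) stop("malformed count in formula: ", text, call. = FALSE)
  out <- tapply(counts, elements, sum)
  new_formula(stats::setNames(as.integer(out), names(out)))
}

new_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (any(counts < 0L)) {
    stop("negative element count in formula", call. = FALSE)
  }
  counts <- counts[order(match(names(counts), names(.ATOMIC_MASS)))]
  # Hill order for display; storage order follows the supported-element table
  structure(counts, class = "elemental_formula")
}

#' Format an elemental formula in Hill notation
#'
#' @param counts An `elemental_formula` (or named integer vector).
#' @return A single string, e.g. `"C26H28O8"`. The empty formula formats
#'   as `""`.
#' @examples
#' format_formula(parse_formula("O4C8H6"))  # "C8H6O4"
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts) == 0L) return("")
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  counts <- counts[hill]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) format_formula(x)

as_formula_counts <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(new_formula(as.integer(x)))
  stop("cannot interpret object as an elemental formula", call. = FALSE)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the monoisotopic atomic mass of the
#' most abundant isotope. Average masses are deliberately not used: every
#' printed oligomer m/z handled by this package is reproduced by
#' monoisotopic arithmetic.
#'
#' @param formula An `elemental_formula`, a formula string, or a character
#'   vector of formula strings (vectorised).
#' @return Mass in Da (numeric, same length as the input when given a
#'   character vector). The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C8H6O4")  # 166.0266
#' monoisotopic_mass("H2O")     # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula) && length(formula) > 1L) {
    return(vapply(formula, monoisotopic_mass, numeric(1), USE.NAMES = FALSE))
  }
  counts <- as_formula_counts(formula)
  if (length(counts) == 0L) return(0)
  sum(.ATOMIC_MASS[names(counts)] * as.numeric(counts))
}

#' Combine formulas with water loss
#'
#' Element-wise sum of the given formulas minus `n_water_removed` H2O —
#' the condensation arithmetic behind ester-bond formation: a linear
#' oligomer of u units loses u − 1 waters, the fully cyclised form loses u.
#'
#' @param parts A list of formulas (strings or `elemental_formula`s).
#' @param n_water_removed Non-negative integer count of waters to subtract.
#' @return An `elemental_formula`. Errors if any element count would go
#'   negative.
#' @examples
#' # cyclic dimer of an aromatic diacid with neopentyl glycol
#' combine_formulas(list("C8H6O4", "C8H6O4", "C5H12O2", "C5H12O2"), 4)
#' @export
combine_formulas <- function(parts, n_water_removed = 0L) {
  stopifnot(length(n_water_removed) == 1L, n_water_removed >= 0)
  parts <- lapply(parts, as_formula_counts)
  total <- integer(0)
  for (p in parts) {
    all_el <- union(names(total), names(p))
    total <- stats::setNames(
      ifelse(is.na(match(all_el, names(total))), 0L, total[match(all_el, names(total))]) +
        ifelse(is.na(match(all_el, names(p))), 0L, p[match(all_el, names(p))]),
      all_el
    )
  }
  h <- if ("H" %in% names(total)) total[["H"]] else 0L
  o <- if ("O" %in% names(total)) total[["O"]] else 0L
  nw <- as.integer(n_water_removed)
  if (h < 2L * nw || o < nw) {
    stop("removing ", nw, " water(s) would give a negative element count",
         call. = FALSE)
  }
  if (nw > 0L) {
    total[["H"]] <- h - 2L * nw
    total[["O"]] <- o - nw
  }
  new_formula(total)
}
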