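# Ionization layer: singly charged adducts in positive mode, deprotonated
# acids for the targeted negative-mode screen. Charge never exceeds |1|;
# every printed oligomer adduct in this problem domain is singly charged.

.ADDUCTS <- tibble::tribble(
  ~adduct,  ~charge, ~mass_delta,
  "M+H",    +1L,      1.007276,
  "M+NH4",  +1L,     18.033823,
  "M+Na",   +1L,     22.989218,
  "M+K",    +1L,     38.963158,
  "M-H",    -1L,     -1.007276
)

#' Supported adduct table
#'
#' @return A tibble with columns `adduct`, `charge`, `mass_delta` (Da).
#'   The deltas are ion masses: proton mass for M+H, and cation mass minus
#'   the electron for M+Na / M+K / M+NH4.
#' @export
adduct_table <- function() .ADDUCTS

#' Positive adduct names used for oligomer screening
#' @return `c("M+H", "M+NH4", "M+Na", "M+K")`
#' @export
positive_adducts <- function() c("M+H", "M+NH4", "M+Na", "M+K")

adduct_delta <- function(adduct) {
  i <- match(adduct, .ADDUCTS$adduct)
  if (anyNA(i)) {
    stop("unsupported adduct name(s): ",
         paste(unique(adduct[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .ADDUCTS$mass_delta[i]
}

#' m/z of an adduct ion
#'
#' For singly charged species the m/z is simply the neutral mass plus the
#' adduct's mass delta.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (vectorised).
#' @param adduct Adduct name(s): `"M+H"`, `"M+NH4"`, `"M+Na"`, `"M+K"`,
#'   `"M-H"`. Recycled against `neutral_mass`.
#' @return m/z in Da.
#' @examples
#' adduct_mz(468.1784, "M+H")   # 469.186 -> printed as 469.2
#' adduct_mz(702.2676, "M+Na")  # 725.257 -> printed as 725.3
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  neutral_mass + adduct_delta(adduct)
}

#' Round half away from zero
#'
#' Printed m/z tables round half away from zero, unlike [round()]'s
#' round-half-to-even; use this when comparing computed values with
#' published one-decimal m/z.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(469.1857)  # 469.2
#' @export
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross a candidate table with an adduct set
#'
#' Expands each neutral oligomer into one row per adduct, sorted by m/z;
#' the deterministic candidate-ion table that peak matching runs against.
#'
#' @param oligomers A tibble with at least `mass` (Da); typically the
#'   output of [enumerate_oligomers()].
#' @param adducts Character vector of adduct names
#'   (default [positive_adducts()]).
#' @return The input columns plus `adduct` and `mz`, sorted by `mz` (ties
#'   by composition string when present).
#' @examples
#' lib <- dplyr::filter(default_monomer_library(), id %in% c("PA", "EG"))
#' build_ion_table(enumerate_oligomers(lib, max_units = 4), "M+H")
#' @export
build_ion_table <- function(oligomers, adducts = positive_adducts()) {
  stopifnot(nrow(oligomers) > 0L, length(adducts) > 0L)
  adduct_delta(adducts)  # validate names early
  out <- tidyr::expand_grid(oligomers, adduct = adducts)
  out$mz <- adduct_mz(out$mass, out$adduct)
  if ("composition" %in% names(out)) {
    dplyr::arrange(out, .data$mz, .data$composition, .data$adduct)
  } else {
    dplyr::arrange(out, .data$mz, .data$adduct)
  }
}

#' Deprotonated precursors for the targeted acid screen
#'
#' One [M-H]- ion per acid monomer (diacids, triacids and hydroxyacids)
#' in the library, as used for targeted negative-mode monitoring of free
#' acid monomers. Exact monoisotopic values are reported; unit-resolution
#' instrument windows quoted around them are centred, not authoritative.
#'
#' @param library A `monomer_library`.
#' @param include_hydroxyacids Include hydroxyacid monomers (default
#'   `FALSE`: the targeted screen covers the polyvalent carboxylic acids).
#' @return A tibble `id`, `name`, `formula`, `neutral_mass`, `adduct`,
#'   `mz`, sorted by `mz`; zero rows if the library has no acids.
#' @examples
#' targeted_acid_precursors(default_monomer_library())
#' @export
targeted_acid_precursors <- function(library, include_hydroxyacids = FALSE) {
  classes <- c("diacid", "triacid", if (include_hydroxyacids) "hydroxyacid")
  acids <- dplyr::filter(library, .data$monomer_class %in% classes)
  tibble::tibble(
    id = acids$id,
    name = acids$name,
    formula = acids$formula,
    neutral_mass = acids$mass,
    adduct = rep("M-H", nrow(acids)),
    mz = adduct_mz(acids$mass, rep("M-H", nrow(acids)))
  ) |>
    dplyr::arrange(.data$mz, .data$id)
}
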