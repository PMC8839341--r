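# MSn product-ion enumeration by ester-bond cleavage arithmetic. The model
# is combinatorial over compositions, not bond-resolved structures: a
# fragment is a sub-multiset of the parent's monomers with a plausible
# number of water equivalents condensed out, observed protonated. This is
# a deliberate heuristic — it reproduces interpreted ester-cleavage
# fragments without attempting mechanism or intensity.

#' Enumerate candidate product ions of a protonated oligomer
#'
#' Only protonated precursors fragment usefully in this scheme; sodiated,
#' ammoniated and potassiated precursors return an empty table with a
#' `note` attribute (the experimental observation this mirrors: no
#' fragmentation from Na+/NH4+ precursors).
#'
#' Candidates are every non-empty sub-composition of the parent, with
#' water-equivalent losses from (units - 1) to (units + 1) — the ester
#' bonds retained inside the fragment plus up to one extra dehydration —
#' capped at what the elemental formula allows. The full parent
#' composition additionally contributes the precursor minus k water ladder
#' (k = 1, 2). All candidate m/z are strictly below the precursor m/z.
#'
#' @param composition Parent composition (string or named counts).
#' @param topology Parent topology (`"cyclic"` or `"linear"`).
#' @param library A `monomer_library`.
#' @param precursor_adduct Adduct of the selected precursor (`"M+H"`
#'   fragments; others yield an empty table).
#' @param max_depth Reserved for multi-stage trees; composition arithmetic
#'   (depth 1) covers every interpreted fragment and is the only level
#'   implemented.
#' @return A tibble sorted by decreasing m/z: `fragment` (composition
#'   string), `n_units`, `n_water_lost`, `mz` (protonated), `loss_mass`
#'   (precursor m/z minus fragment m/z), `description`.
#' @examples
#' frs <- enumerate_fragments("2PA+2NPG", "cyclic")
#' round(frs$mz[frs$n_units <= 1], 2)  # includes 149.02
#' @export
enumerate_fragments <- function(composition, topology = c("cyclic", "linear"),
                                library = default_monomer_library(),
                                precursor_adduct = "M+H", max_depth = 1L) {
  topology <- match.arg(topology)
  if (is.character(composition) && is.null(names(composition))) {
    composition <- parse_composition(composition)
  }
  empty <- tibble::tibble(fragment = character(), n_units = integer(),
                          n_water_lost = integer(), mz = numeric(),
                          loss_mass = numeric(), description = character())
  if (!identical(precursor_adduct, "M+H")) {
    return(structure(empty,
                     note = "no fragmentation modelled for non-protonated precursors"))
  }
  composition <- composition[composition > 0L]
  idx <- match(names(composition), library$id)
  if (anyNA(idx)) stop("unknown monomer id(s)", call. = FALSE)
  parent_mass <- neutral_mass(composition, topology, library)
  parent_bonds <- ester_bond_count(composition, topology)
  precursor_mz <- adduct_mz(parent_mass, "M+H")
  proton <- adduct_delta("M+H")

  # all sub-multisets of the parent counts
  sub_counts <- do.call(tidyr::expand_grid,
                        stats::setNames(lapply(composition, function(k) 0:k),
                                        names(composition)))
  sub_counts <- sub_counts[rowSums(sub_counts) > 0L, , drop = FALSE]
  masses <- library$mass[idx]
  formulas <- library$formula[idx]

  rows <- purrr::map_dfr(seq_len(nrow(sub_counts)), function(r) {
    ct <- as.integer(sub_counts[r, ])
    names(ct) <- names(composition)
    u <- sum(ct)
    full_parent <- all(ct == composition)
    k_max <- if (full_parent) parent_bonds + 2L else u + 1L
    ks <- max(0L, u - 1L):k_max
    f <- combine_formulas(as.list(rep(formulas, ct)), 0L)
    h <- if ("H" %in% names(f)) f[["H"]] else 0L
    o <- if ("O" %in% names(f)) f[["O"]] else 0L
    ks <- ks[2L * ks <= h & ks <= o]
    if (length(ks) == 0L) return(NULL)
    mzs <- sum(masses * ct) - ks * water_mass() + proton
    keep <- mzs < precursor_mz - 1e-9
    if (!any(keep)) return(NULL)
    comp_str <- composition_string(ct, library)
    tibble::tibble(
      fragment = comp_str,
      n_units = u,
      n_water_lost = ks[keep],
      mz = mzs[keep],
      loss_mass = precursor_mz - mzs[keep],
      description = sprintf("%s - %d H2O, protonated", comp_str, ks[keep])
    )
  })
  if (nrow(rows) == 0L) return(empty)
  rows |>
    dplyr::distinct(.data$fragment, .data$n_water_lost, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$mz), .data$fragment)
}

#' Annotate observed product ions against fragment candidates
#'
#' Each observed m/z is matched to the nearest candidate within `tol`
#' (default 0.5 Da: product ions from a unit-resolution trap are reported
#' at integer precision). Unmatched ions are kept with NA candidate
#' columns.
#'
#' @param observed Numeric vector of observed product-ion m/z values.
#' @param candidates Tibble from [enumerate_fragments()].
#' @param tol Matching tolerance in Da.
#' @return A tibble: `observed_mz`, `matched` (logical), candidate columns
#'   (`fragment`, `n_water_lost`, `mz`, `description`), `error_da`.
#' @examples
#' frs <- enumerate_fragments("2PA+NPG+HD", "cyclic")
#' annotate_product_ions(c(415, 231, 149), frs)
#' @export
annotate_product_ions <- function(observed, candidates, tol = 0.5) {
  if (length(observed) == 0L) {
    return(tibble::tibble(observed_mz = numeric(), matched = logical(),
                          fragment = character(), n_water_lost = integer(),
                          mz = numeric(), description = character(),
                          error_da = numeric()))
  }
  purrr::map_dfr(observed, function(om) {
    if (nrow(candidates) > 0L) {
      d <- abs(candidates$mz - om)
      best <- which.min(d)
    } else {
      best <- integer(0)
    }
    if (length(best) == 1L && abs(candidates$mz[best] - om) <= tol) {
      tibble::tibble(observed_mz = om, matched = TRUE,
                     fragment = candidates$fragment[best],
                     n_water_lost = candidates$n_water_lost[best],
                     mz = candidates$mz[best],
                     description = candidates$description[best],
                     error_da = om - candidates$mz[best])
    } else {
      tibble::tibble(observed_mz = om, matched = FALSE,
                     fragment = NA_character_, n_water_lost = NA_integer_,
                     mz = NA_real_, description = NA_character_,
                     error_da = NA_real_)
    }
  })
}
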