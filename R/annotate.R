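# Peak annotation: match observed peaks against the candidate-ion table
# under a ppm or Da tolerance; every candidate within tolerance is kept
# (isobaric ambiguity is information, not noise), rank 1 marks the
# smallest mass error.

n_monomer_types <- function(composition) {
  stringr::str_count(composition, stringr::fixed("+")) + 1L
}

#' Match peaks against a candidate-ion table
#'
#' Every (peak, ion) pair within tolerance is reported. Within a peak,
#' matches are ranked by absolute mass error; ties break toward fewer
#' distinct monomer types, then fewer units, then the canonical
#' composition string. Peaks without any candidate are flagged in the
#' `unassigned` attribute.
#'
#' @param peaks A [peaklist()] (or a data frame with `mz`, `intensity`;
#'   auto-sorted with a warning if needed).
#' @param ions Candidate-ion tibble from [build_ion_table()] (columns
#'   `mz`, `adduct`, and typically `composition`, `topology`, `n_units`,
#'   `mass`).
#' @param tol,tol_unit Matching tolerance; defaults to the peak list's own
#'   tolerance model (10 ppm MALDI, 0.3 Da ion trap).
#' @return A tibble with one row per (peak, candidate) pair: `peak_idx`,
#'   `peak_mz`, `intensity`, the candidate columns, `error_da`, `error_ppm`
#'   (observed minus theoretical, sign preserved), `rank`, and
#'   `isobaric_note` listing co-exact-mass compositions. Attribute
#'   `unassigned`: integer indices of unmatched peaks.
#' @examples
#' lib <- dplyr::filter(default_monomer_library(), id %in% c("PA", "NPG"))
#' ions <- build_ion_table(enumerate_oligomers(lib, max_units = 4))
#' match_peaks(peaklist(491.17, instrument = "ion_trap"), ions)
#' @export
match_peaks <- function(peaks, ions, tol = NULL, tol_unit = c("da", "ppm")) {
  stopifnot(nrow(ions) > 0L)
  tolerance <- peak_tolerance(peaks, tol, tol_unit)
  if (is.unsorted(peaks$mz)) {
    warning("peak list not sorted by m/z; sorting", call. = FALSE)
    peaks <- peaks[order(peaks$mz), ]
  }
  ions <- dplyr::arrange(ions, .data$mz)
  # flag candidates sharing an exact theoretical m/z (isobaric compositions)
  if ("composition" %in% names(ions)) {
    key <- paste(ions$adduct, sprintf("%.6f", ions$mz))
    sizes <- stats::ave(seq_along(key), key, FUN = length)
    labels <- tapply(ions$composition, key,
                     function(x) paste(sort(unique(x)), collapse = "; "))
    ions$isobaric_note <- ifelse(sizes > 1L, unname(labels[key]), NA_character_)
  }
  tol_da <- tolerance_da(peaks$mz, tolerance)
  lo <- findInterval(peaks$mz - tol_da, ions$mz) + 1L
  hi <- findInterval(peaks$mz + tol_da, ions$mz)
  n_hits <- pmax(0L, hi - lo + 1L)
  peak_idx <- rep(seq_len(nrow(peaks)), n_hits)
  ion_idx <- unlist(lapply(seq_len(nrow(peaks)), function(i) {
    if (n_hits[i] == 0L) integer(0) else lo[i]:hi[i]
  }), use.names = FALSE)
  out <- dplyr::bind_cols(
    tibble::tibble(peak_idx = peak_idx,
                   peak_mz = peaks$mz[peak_idx],
                   intensity = peaks$intensity[peak_idx]),
    ions[ion_idx, setdiff(names(ions), c("peak_idx", "peak_mz", "intensity")),
         drop = FALSE]
  )
  out$error_da <- out$peak_mz - out$mz
  out$error_ppm <- out$error_da / out$mz * 1e6
  rank_keys <- list(abs(out$error_da))
  if ("composition" %in% names(out)) {
    rank_keys <- c(rank_keys, list(n_monomer_types(out$composition)))
  }
  if ("n_units" %in% names(out)) rank_keys <- c(rank_keys, list(out$n_units))
  if ("composition" %in% names(out)) rank_keys <- c(rank_keys, list(out$composition))
  ord <- do.call(order, c(list(out$peak_idx), rank_keys))
  out <- out[ord, ]
  out <- out |>
    dplyr::group_by(.data$peak_idx) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  structure(dplyr::rename(out, theoretical_mz = "mz"),
            unassigned = setdiff(seq_len(nrow(peaks)), unique(out$peak_idx)))
}

#' Default configuration for [annotate_run()]
#'
#' @param max_units,max_mass,topologies,allow_monools Enumeration bounds,
#'   see [enumerate_oligomers()].
#' @param adducts Adduct set for the ion table.
#' @param tol,tol_unit Matching tolerance override (default: the peak
#'   list's own tolerance model).
#' @return A named list.
#' @export
annotation_config <- function(max_units = 8L, max_mass = 1000,
                              topologies = c("cyclic", "linear"),
                              adducts = positive_adducts(),
                              tol = NULL, tol_unit = "da",
                              allow_monools = FALSE) {
  list(max_units = max_units, max_mass = max_mass, topologies = topologies,
       adducts = adducts, tol = tol, tol_unit = tol_unit,
       allow_monools = allow_monools)
}

#' Annotate a peak list end to end
#'
#' The pipeline wrapper: enumerate feasible oligomers from the library,
#' build the adduct-ion table, match the peaks, and summarise. The
#' "tentative identification" step of a migrant screen.
#'
#' @param peaks A [peaklist()].
#' @param library A `monomer_library` (default the shipped library).
#' @param config A list from [annotation_config()].
#' @return An object of class `oligomer_annotation`: a list with
#'   `matches` (tibble, see [match_peaks()]), `unassigned` (tibble of
#'   unmatched peaks), `peaks`, `candidates` (the ion table), `summary`
#'   (one-row tibble) and `config`. Use [generics::tidy()] for the match
#'   table and [generics::glance()] for the summary row.
#' @examples
#' lib <- dplyr::filter(default_monomer_library(), id %in% c("PA", "NPG"))
#' pk <- peaklist(c(469.19, 491.17), c(100, 80), instrument = "ion_trap")
#' annotate_run(pk, lib)
#' @export
annotate_run <- function(peaks, library = default_monomer_library(),
                         config = annotation_config()) {
  oligomers <- enumerate_oligomers(
    library, max_units = config$max_units, max_mass = config$max_mass,
    topologies = config$topologies, allow_monools = config$allow_monools
  )
  matches <- if (nrow(peaks) == 0L) {
    structure(tibble::tibble(), unassigned = integer(0))
  } else {
    ions <- build_ion_table(oligomers, config$adducts)
    match_peaks(peaks, ions, tol = config$tol, tol_unit = config$tol_unit)
  }
  unassigned_idx <- attr(matches, "unassigned") %||% integer(0)
  n_peaks <- nrow(peaks)
  n_assigned <- n_peaks - length(unassigned_idx)
  res <- list(
    matches = matches,
    unassigned = tibble::as_tibble(peaks)[unassigned_idx, , drop = FALSE],
    peaks = peaks,
    candidates_n = nrow(oligomers),
    summary = tibble::tibble(
      n_peaks = n_peaks,
      n_assigned = n_assigned,
      assignment_rate = if (n_peaks > 0L) n_assigned / n_peaks else NA_real_,
      n_compositions = nrow(oligomers)
    ),
    config = config
  )
  class(res) <- "oligomer_annotation"
  res
}

#' @export
print.oligomer_annotation <- function(x, ...) {
  s <- x$summary
  cat("<oligomer_annotation> ", s$n_assigned, "/", s$n_peaks,
      " peaks assigned (", round(100 * s$assignment_rate, 1), "%), ",
      s$n_compositions, " candidate compositions\n", sep = "")
  invisible(x)
}

#' Tidy the match table of an annotation run
#' @param x An `oligomer_annotation`.
#' @param ... Unused.
#' @return The match tibble (one row per peak-candidate pair).
#' @method tidy oligomer_annotation
#' @export
tidy.oligomer_annotation <- function(x, ...) tibble::as_tibble(x$matches)

#' One-row summary of an annotation run
#' @param x An `oligomer_annotation`.
#' @param ... Unused.
#' @return A one-row tibble: `n_peaks`, `n_assigned`, `assignment_rate`,
#'   `n_compositions`.
#' @method glance oligomer_annotation
#' @export
glance.oligomer_annotation <- function(x, ...) x$summary
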