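# Homologous-series analysis: arithmetic progressions at repeat-unit
# masses in a MALDI spectrum, monomer-exchange mass deltas between series,
# and inference of the monomer set behind a spectrum. This is the manual
# repeat-unit reasoning of polymer MALDI work cast as a greedy algorithm.

#' Candidate repeat units of a monomer library
#'
#' A repeat unit is one diacid + one diol residue pair (two waters
#' removed) or one ring-opened hydroxyacid residue (one water removed) —
#' the mass that separates consecutive members of a homologous oligomer
#' series. Units are deduplicated by mass so isobaric monomers collapse
#' into one labelled unit.
#'
#' @param library A `monomer_library`.
#' @return A tibble: `unit` (label, isobaric alternatives joined by `/`),
#'   `mass` (Da), `acid_group`, `diol_group` (representative ids; the diol
#'   slot is `NA` for hydroxyacid units), `acid_ids`, `diol_ids`
#'   (list-columns of contributing monomer ids).
#' @examples
#' lib <- dplyr::filter(default_monomer_library(), id %in% c("PA", "IPA", "NPG"))
#' candidate_repeat_units(lib)  # one unit at 234.0892
#' @export
candidate_repeat_units <- function(library) {
  groups <- isobaric_groups(library)
  acids <- dplyr::filter(library, .data$monomer_class == "diacid")
  diols <- dplyr::filter(library, .data$monomer_class == "diol")
  has <- dplyr::filter(library, .data$monomer_class == "hydroxyacid")
  pair_units <- if (nrow(acids) > 0L && nrow(diols) > 0L) {
    tidyr::expand_grid(acid = acids$id, diol = diols$id) |>
      dplyr::mutate(
        mass = library$mass[match(.data$acid, library$id)] +
          library$mass[match(.data$diol, library$id)] - 2 * water_mass(),
        hydroxyacid = NA_character_
      )
  } else {
    tibble::tibble(acid = character(), diol = character(),
                   mass = numeric(), hydroxyacid = character())
  }
  ha_units <- tibble::tibble(
    acid = NA_character_, diol = NA_character_,
    mass = has$mass - water_mass(), hydroxyacid = has$id
  )
  units <- dplyr::bind_rows(pair_units, ha_units)
  if (nrow(units) == 0L) {
    return(tibble::tibble(unit = character(), mass = numeric(),
                          acid_group = character(), diol_group = character(),
                          acid_ids = list(), diol_ids = list()))
  }
  glabel <- function(ids) {
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L) return(NA_character_)
    paste(unique(groups$group_label[match(ids, groups$id)]), collapse = "/")
  }
  grep_id <- function(ids) {
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L) return(NA_character_)
    paste(unique(groups$group_id[match(ids, groups$id)]), collapse = "/")
  }
  units |>
    dplyr::group_by(mkey = sprintf("%.6f", .data$mass)) |>
    dplyr::summarise(
      mass = .data$mass[1L],
      unit = {
        a <- glabel(.data$acid); d <- glabel(.data$diol); h <- glabel(.data$hydroxyacid)
        pair_lab <- if (!is.na(a) && !is.na(d)) paste0(a, "+", d) else NA_character_
        paste(stats::na.omit(c(pair_lab, h)), collapse = "/")
      },
      acid_group = grep_id(c(.data$acid, .data$hydroxyacid)),
      diol_group = grep_id(.data$diol),
      acid_ids = list(unique(stats::na.omit(c(.data$acid, .data$hydroxyacid)))),
      diol_ids = list(unique(stats::na.omit(.data$diol))),
      .groups = "drop"
    ) |>
    dplyr::select("unit", "mass", "acid_group", "diol_group", "acid_ids",
                  "diol_ids") |>
    dplyr::arrange(.data$mass)
}

#' Detect homologous series at one repeat-unit mass
#'
#' Greedy nearest-peak chaining: starting from every peak that has no
#' predecessor one repeat mass below it, extend by repeatedly taking the
#' peak closest to (current + unit) within `tol`. Chains with at least
#' `min_length` members are reported; chains over different units may
#' overlap. Greedy chaining mirrors the manual reading of a polymer
#' spectrum and is documented as a limitation for very dense spectra.
#'
#' @param peaks A [peaklist()] (or data frame with `mz`, `intensity`).
#' @param unit Repeat-unit mass in Da, or a one-row tibble from
#'   [candidate_repeat_units()].
#' @param tol Spacing tolerance in Da (default 0.2, reflector MALDI).
#' @param min_length Minimum members per series (default 3).
#' @return A tibble: `series_id`, `unit`, `unit_mass`, `base_mz`,
#'   `n_members`, `member_idx`, `member_mz` (list-columns),
#'   `total_intensity`, `mad_spacing` (mean absolute deviation of the
#'   observed spacings from the unit mass).
#' @examples
#' pk <- peaklist(c(469.19, 703.27, 937.36, 1171.45))
#' detect_series(pk, 234.0892)
#' @export
detect_series <- function(peaks, unit, tol = 0.2, min_length = 3L) {
  unit_label <- NA_character_
  if (is.data.frame(unit)) {
    unit_label <- unit$unit[1L]
    unit <- unit$mass[1L]
  }
  stopifnot(is.numeric(unit), length(unit) == 1L, unit > 0)
  mz <- sort(peaks$mz)
  intensity <- peaks$intensity[order(peaks$mz)]
  n <- length(mz)
  empty <- tibble::tibble(series_id = integer(), unit = character(),
                          unit_mass = numeric(), base_mz = numeric(),
                          n_members = integer(), member_idx = list(),
                          member_mz = list(), total_intensity = numeric(),
                          mad_spacing = numeric())
  if (n == 0L) return(empty)
  nearest_next <- function(from_mz) {
    target <- from_mz + unit
    lo <- findInterval(target - tol, mz) + 1L
    hi <- findInterval(target + tol, mz)
    if (lo > hi) return(NA_integer_)
    cand <- lo:hi
    cand[which.min(abs(mz[cand] - target))]
  }
  has_predecessor <- vapply(seq_len(n), function(i) {
    target <- mz[i] - unit
    lo <- findInterval(target - tol, mz) + 1L
    hi <- findInterval(target + tol, mz)
    lo <= hi
  }, logical(1))
  chains <- list()
  for (start in which(!has_predecessor)) {
    chain <- start
    repeat {
      nxt <- nearest_next(mz[chain[length(chain)]])
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
    }
    if (length(chain) >= min_length) chains[[length(chains) + 1L]] <- chain
  }
  if (length(chains) == 0L) return(empty)
  umass <- unit
  tibble::tibble(
    series_id = seq_along(chains),
    unit = unit_label,
    unit_mass = umass,
    base_mz = vapply(chains, function(ch) mz[ch[1L]], numeric(1)),
    n_members = lengths(chains),
    member_idx = chains,
    member_mz = lapply(chains, function(ch) mz[ch]),
    total_intensity = vapply(chains, function(ch) sum(intensity[ch]), numeric(1)),
    mad_spacing = vapply(chains, function(ch) {
      mean(abs(diff(mz[ch]) - umass))
    }, numeric(1))
  )
}

#' Detect series for every candidate repeat unit of a library
#'
#' @inheritParams detect_series
#' @param library A `monomer_library`.
#' @return Row-bound [detect_series()] results joined with the unit table
#'   columns (`acid_group`, `diol_group`).
#' @export
detect_all_series <- function(peaks, library, tol = 0.2, min_length = 3L) {
  units <- candidate_repeat_units(library)
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    hits <- detect_series(peaks, units[i, ], tol = tol, min_length = min_length)
    if (nrow(hits) == 0L) return(hits)
    hits$acid_group <- units$acid_group[i]
    hits$diol_group <- units$diol_group[i]
    hits
  })
}

#' Monomer-exchange mass deltas supported by a spectrum
#'
#' Swapping one diol for another inside an oligomer shifts the mass by the
#' difference of the diol masses (e.g. +14 Da for NPG to HD, +40 Da for
#' NPG to CHDM, -42 Da for NPG to EG). For every ordered pair of
#' non-isobaric diols (and triols) in the library, counts the peak pairs
#' whose spacing matches the exchange delta within `tol`.
#'
#' @param peaks A [peaklist()] or data frame with `mz` (at least 2 peaks).
#' @param library A `monomer_library`.
#' @param tol Spacing tolerance in Da (default 0.2).
#' @return A tibble: `monomer_out`, `monomer_in`, `delta` (mass(in) -
#'   mass(out), Da), `n_pairs`.
#' @examples
#' pk <- peaklist(c(491.17, 505.19))
#' lib <- dplyr::filter(default_monomer_library(), id %in% c("PA", "NPG", "HD"))
#' detect_exchange_deltas(pk, lib)
#' @export
detect_exchange_deltas <- function(peaks, library, tol = 0.2) {
  stopifnot(nrow(peaks) >= 2L)
  diols <- dplyr::filter(library, .data$monomer_class %in% c("diol", "triol"))
  prs <- tidyr::expand_grid(monomer_out = diols$id, monomer_in = diols$id) |>
    dplyr::filter(.data$monomer_out != .data$monomer_in) |>
    dplyr::mutate(delta = diols$mass[match(.data$monomer_in, diols$id)] -
                    diols$mass[match(.data$monomer_out, diols$id)]) |>
    dplyr::filter(abs(.data$delta) > 1e-9)
  mz <- sort(peaks$mz)
  prs$n_pairs <- vapply(prs$delta, function(d) {
    target <- mz + abs(d)
    lo <- findInterval(target - tol, mz) + 1L
    hi <- findInterval(target + tol, mz)
    sum(pmax(0L, hi - lo + 1L))
  }, numeric(1)) |> as.integer()
  dplyr::arrange(prs, dplyr::desc(.data$n_pairs), .data$delta)
}

#' Infer the monomer set behind a MALDI spectrum
#'
#' Combines repeat-unit series detection and exchange-delta evidence:
#' for each acid (isobaric group), the candidate subset collects every
#' diol whose acid+diol repeat unit supports a series, plus hydroxyacids
#' with their own series. Subsets are scored by (series members
#' explained, exchange-delta confirmations); within a subset, diols are
#' ordered by the summed intensity of the series members they explain —
#' an ordinal proportion ranking, not a quantification.
#'
#' @inheritParams detect_all_series
#' @param min_length Minimum series length (default 3).
#' @param min_intensity_fraction Evidence floor: a diol (or hydroxyacid)
#'   stays in a subset only if the summed intensity its series explain is
#'   at least this fraction of the strongest diol's in the same subset
#'   (default 0.01). Screens out coincidental chains over weak peaks in
#'   dense spectra.
#' @return A tibble, one row per candidate subset, ranked by explained
#'   intensity: `rank`, `monomers` (list-column of representative monomer
#'   ids), `label`, `n_series`, `n_series_members`, `explained_intensity`,
#'   `n_exchange_pairs`, `diol_ranking` (list-column, representative diol
#'   ids by decreasing explained intensity).
#' @export
infer_monomer_set <- function(peaks, library, tol = 0.2, min_length = 3L,
                              min_intensity_fraction = 0.01) {
  stopifnot(nrow(peaks) > 0L)
  groups <- isobaric_groups(library)
  hits <- detect_all_series(peaks, library, tol = tol, min_length = min_length)
  empty <- tibble::tibble(rank = integer(), monomers = list(),
                          label = character(), n_series = integer(),
                          n_series_members = integer(),
                          n_exchange_pairs = integer(), diol_ranking = list())
  if (nrow(hits) == 0L) return(empty)
  exch <- if (nrow(peaks) >= 2L) detect_exchange_deltas(peaks, library, tol) else
    tibble::tibble(monomer_out = character(), monomer_in = character(),
                   delta = numeric(), n_pairs = integer())
  ha_groups <- unique(groups$group_id[groups$monomer_class == "hydroxyacid"])
  subsets <- hits |>
    dplyr::filter(!(.data$acid_group %in% ha_groups)) |>
    dplyr::group_by(.data$acid_group) |>
    dplyr::group_map(function(g, key) {
      diol_score <- g |>
        dplyr::group_by(.data$diol_group) |>
        dplyr::summarise(intensity = sum(.data$total_intensity),
                         members = sum(.data$n_members), .groups = "drop") |>
        dplyr::arrange(dplyr::desc(.data$intensity))
      floor_int <- min_intensity_fraction * max(diol_score$intensity, 0)
      diol_score <- diol_score[diol_score$intensity >= floor_int, , drop = FALSE]
      g <- g[g$diol_group %in% diol_score$diol_group |
               is.na(g$diol_group), , drop = FALSE]
      ha_hits <- hits[hits$acid_group %in% ha_groups, , drop = FALSE]
      ha_hits <- ha_hits[ha_hits$total_intensity >= floor_int, , drop = FALSE]
      diol_ids_rep <- diol_score$diol_group[!is.na(diol_score$diol_group)]
      member_ids <- c(key$acid_group, diol_ids_rep, unique(ha_hits$acid_group))
      exch_in <- exch |>
        dplyr::mutate(
          og = groups$group_id[match(.data$monomer_out, groups$id)],
          ig = groups$group_id[match(.data$monomer_in, groups$id)]
        ) |>
        dplyr::filter(.data$og %in% diol_ids_rep, .data$ig %in% diol_ids_rep,
                      .data$og < .data$ig)
      tibble::tibble(
        monomers = list(member_ids),
        label = paste(member_ids, collapse = ", "),
        n_series = nrow(g) + nrow(ha_hits),
        n_series_members = sum(g$n_members) + sum(ha_hits$n_members),
        explained_intensity = sum(g$total_intensity) + sum(ha_hits$total_intensity),
        n_exchange_pairs = sum(exch_in$n_pairs),
        diol_ranking = list(diol_ids_rep)
      )
    }) |>
    dplyr::bind_rows()
  # strongest explained signal wins: series over dominant peaks are the
  # evidence an analyst trusts, member counts only break ties
  subsets |>
    dplyr::arrange(dplyr::desc(.data$explained_intensity),
                   dplyr::desc(.data$n_series_members),
                   dplyr::desc(.data$n_exchange_pairs), .data$label) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "monomers", "label", "n_series",
                  "n_series_members", "explained_intensity",
                  "n_exchange_pairs", "diol_ranking")
}
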