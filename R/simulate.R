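# Seeded synthetic MALDI and MSn spectra from a declared formulation, so
# every pipeline stage is testable without instrument data. The intensity
# model (product of monomer proportions with log-normal jitter) and the
# noise model (uniform m/z, exponential intensity) are inventions that
# exist to exercise ranking and robustness — no claim of realism beyond
# the series structure and the adduct/mass-error behaviour.

#' Declare a synthetic coating formulation
#'
#' @param monomers A tibble (or named numeric vector) of monomer ids and
#'   relative proportions; proportions are normalised to sum to 1.
#' @param fraction_cyclic Weight given to cyclic topologies (default 0.8:
#'   most migrating oligomers are ring-closed because they lack free
#'   functional groups).
#' @param unit_range Oligomer size range in units (default 2 to 8).
#' @param adducts Named weight vector over adduct names: the relative
#'   abundance of each cationised form of a neutral. Default is strongly
#'   Na-dominant, as with a sodium-salt cationization agent:
#'   Na 0.9, H 0.05, NH4 0.025, K 0.025.
#' @param mass_error List `list(value=, unit=)` with unit `"ppm"` or
#'   `"da"`: the *accuracy* of the instrument, read as a ~3-sigma window
#'   (the Gaussian error applied uses sigma = value / 3). Default 10 ppm.
#' @param n_noise Number of chemical-noise peaks (default 0).
#' @param noise_intensity Mean of the exponential noise-intensity law,
#'   as a fraction of the maximum signal intensity (default 0.05).
#' @param intensity_sdlog Log-normal jitter sigma on signal intensities
#'   (default 0.3).
#' @param min_rel_intensity Detector dynamic-range floor: signal species
#'   whose expected intensity falls below this fraction of the strongest
#'   species are not observed (default 1e-3).
#' @param library Monomer library the ids refer to.
#' @return A list of class `synthetic_formulation`.
#' @examples
#' formulation_cm1()
#' @export
synthetic_formulation <- function(monomers,
                                  fraction_cyclic = 0.8,
                                  unit_range = c(2L, 8L),
                                  adducts = c("M+Na" = 0.9, "M+H" = 0.05,
                                              "M+NH4" = 0.025, "M+K" = 0.025),
                                  mass_error = list(value = 10, unit = "ppm"),
                                  n_noise = 0L,
                                  noise_intensity = 0.05,
                                  intensity_sdlog = 0.3,
                                  min_rel_intensity = 1e-3,
                                  library = default_monomer_library()) {
  if (is.numeric(monomers) && !is.null(names(monomers))) {
    monomers <- tibble::tibble(id = names(monomers), proportion = unname(monomers))
  }
  stopifnot(all(c("id", "proportion") %in% names(monomers)),
            all(monomers$proportion >= 0), sum(monomers$proportion) > 0,
            length(unit_range) == 2L, unit_range[1] >= 1L)
  if (!all(monomers$id %in% library$id)) {
    stop("formulation references monomer id(s) not in the library", call. = FALSE)
  }
  monomers$proportion <- monomers$proportion / sum(monomers$proportion)
  adducts <- adducts / sum(adducts)
  structure(list(monomers = tibble::as_tibble(monomers),
                 fraction_cyclic = fraction_cyclic,
                 unit_range = as.integer(unit_range), adducts = adducts,
                 mass_error = mass_error, n_noise = as.integer(n_noise),
                 noise_intensity = noise_intensity,
                 intensity_sdlog = intensity_sdlog,
                 min_rel_intensity = min_rel_intensity,
                 library = library),
            class = "synthetic_formulation")
}

#' Reference formulations for the two spectral patterns emulated
#'
#' `formulation_cm1()`: a phthalic-type acid with NPG, HD and BD diols
#' plus a caprolactone additive series — the pattern with ±14 Da exchange
#' groups. `formulation_cm2()`: the same acid with NPG, CHDM and EG — the
#' pattern with +40 / −42 Da exchange groups.
#'
#' @param ... Overrides passed to [synthetic_formulation()].
#' @return A `synthetic_formulation`.
#' @export
formulation_cm1 <- function(...) {
  synthetic_formulation(
    c(PA = 0.45, NPG = 0.25, HD = 0.15, BD = 0.10, CL = 0.05), ...
  )
}

#' @rdname formulation_cm1
#' @export
formulation_cm2 <- function(...) {
  synthetic_formulation(
    c(PA = 0.50, NPG = 0.25, CHDM = 0.15, EG = 0.10), ...
  )
}

#' Simulate a MALDI-TOF peak list
#'
#' Enumerates the feasible oligomers of the formulation's monomers within
#' the unit range and emits one peak per (oligomer, adduct) pair: the
#' expected intensity is the product of the monomers' proportions times
#' the topology weight times the adduct-distribution weight (each neutral
#' shows all its cationised forms at characteristic ratios, as in real
#' MALDI), with species below the dynamic-range floor unobserved.
#' Log-normal intensity jitter and Gaussian m/z error
#' (sigma = accuracy / 3) are applied, peaks are clipped to the MALDI
#' window (m/z 350-4000), and uniform-m/z noise peaks with exponential
#' intensities are appended. Fully reproducible per seed.
#'
#' @param formulation A `synthetic_formulation`.
#' @param seed Integer seed (mandatory: all randomness flows from it).
#' @return A list: `peaks` (a [peaklist()], MALDI instrument tag) and
#'   `truth` (tibble mapping each signal peak to `composition`,
#'   `topology`, `adduct`, `mz_true`; noise peaks have NA composition).
#' @examples
#' sim <- simulate_maldi_peaklist(formulation_cm1(), seed = 1)
#' head(sim$truth)
#' @export
simulate_maldi_peaklist <- function(formulation, seed) {
  stopifnot(inherits(formulation, "synthetic_formulation"))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  f <- formulation
  lib <- f$library[f$library$id %in% f$monomers$id, , drop = FALSE]
  if (nrow(lib) == 0L) stop("empty formulation", call. = FALSE)
  window <- .INSTRUMENTS$maldi_tof$window
  oligos <- enumerate_oligomers(lib, max_units = f$unit_range[2],
                                max_mass = window[2],
                                min_units = f$unit_range[1])
  prop <- f$monomers$proportion[match(lib$id, f$monomers$id)]
  names(prop) <- lib$id
  base_int <- vapply(oligos$composition, function(cs) {
    ct <- parse_composition(cs)
    prod(prop[names(ct)]^ct)
  }, numeric(1), USE.NAMES = FALSE)
  topo_w <- ifelse(oligos$topology == "cyclic", f$fraction_cyclic,
                   1 - f$fraction_cyclic)
  ion <- tidyr::expand_grid(
    i = seq_len(nrow(oligos)),
    adduct = names(f$adducts)
  )
  ion$expected <- base_int[ion$i] * topo_w[ion$i] * unname(f$adducts[ion$adduct])
  ion$mz_true <- adduct_mz(oligos$mass[ion$i], ion$adduct)
  # clip to the detection window first: the dynamic-range floor is
  # relative to the strongest observable peak
  ion <- ion[ion$mz_true >= window[1] & ion$mz_true <= window[2], , drop = FALSE]
  ion <- ion[ion$expected >= f$min_rel_intensity * max(ion$expected, 0) &
               ion$expected > 0, , drop = FALSE]
  withr::with_seed(seed, {
    intensity <- 1e4 * ion$expected *
      stats::rlnorm(nrow(ion), 0, f$intensity_sdlog)
    mz_true <- ion$mz_true
    sigma_da <- if (f$mass_error$unit == "ppm") {
      mz_true * (f$mass_error$value / 3) * 1e-6
    } else {
      rep(f$mass_error$value / 3, length(mz_true))
    }
    mz_obs <- mz_true + stats::rnorm(length(mz_true), 0, sigma_da)
    truth <- tibble::tibble(
      composition = oligos$composition[ion$i],
      topology = oligos$topology[ion$i],
      adduct = ion$adduct, mz_true = mz_true, mz = mz_obs,
      intensity = intensity
    )
    truth <- truth[truth$mz >= window[1] & truth$mz <= window[2], , drop = FALSE]
    if (f$n_noise > 0L) {
      lo <- window[1]
      hi <- min(window[2], max(truth$mz, window[1]) + 200)
      noise <- tibble::tibble(
        composition = NA_character_, topology = NA_character_,
        adduct = NA_character_, mz_true = NA_real_,
        mz = stats::runif(f$n_noise, lo, hi),
        intensity = stats::rexp(f$n_noise,
                                1 / (f$noise_intensity * max(truth$intensity, 1)))
      )
      truth <- dplyr::bind_rows(truth, noise)
    }
    truth <- dplyr::arrange(truth, .data$mz)
    list(
      peaks = peaklist(truth$mz, truth$intensity, instrument = "maldi_tof"),
      truth = truth
    )
  })
}

#' Simulate an MSn product-ion spectrum
#'
#' Protonated precursors yield a subset of the ester-cleavage candidates
#' from [enumerate_fragments()] — always including the three most massive
#' candidates, each remaining candidate kept with probability
#' `p_detect` — with log-normal intensity jitter. Sodiated / ammoniated /
#' potassiated precursors yield an empty product list.
#'
#' @inheritParams enumerate_fragments
#' @param seed Integer seed (mandatory).
#' @param p_detect Detection probability for non-guaranteed candidates
#'   (default 0.5).
#' @return A list: `precursor` (one-row tibble: composition, topology,
#'   adduct, mz) and `products` (tibble `mz`, `intensity`, `fragment`).
#' @examples
#' simulate_msn_spectrum("2PA+2NPG", "cyclic", seed = 1)$products
#' @export
simulate_msn_spectrum <- function(composition, topology = c("cyclic", "linear"),
                                  library = default_monomer_library(),
                                  precursor_adduct = "M+H", seed,
                                  p_detect = 0.5) {
  topology <- match.arg(topology)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.character(composition) && is.null(names(composition))) {
    composition <- parse_composition(composition)
  }
  pre_mz <- adduct_mz(neutral_mass(composition, topology, library),
                      precursor_adduct)
  precursor <- tibble::tibble(
    composition = composition_string(composition, library),
    topology = topology, adduct = precursor_adduct, mz = pre_mz
  )
  cand <- enumerate_fragments(composition, topology, library, precursor_adduct)
  products <- withr::with_seed(seed, {
    if (nrow(cand) == 0L) {
      tibble::tibble(mz = numeric(), intensity = numeric(),
                     fragment = character())
    } else {
      cand <- dplyr::arrange(cand, dplyr::desc(.data$mz))
      guaranteed <- seq_len(min(3L, nrow(cand)))
      others <- setdiff(seq_len(nrow(cand)), guaranteed)
      keep <- c(guaranteed, others[stats::runif(length(others)) < p_detect])
      prod_tbl <- cand[sort(keep), , drop = FALSE]
      tibble::tibble(
        mz = prod_tbl$mz,
        intensity = 100 * stats::rlnorm(nrow(prod_tbl), 0, 0.5),
        fragment = prod_tbl$fragment
      )
    }
  })
  list(precursor = precursor, products = products)
}
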