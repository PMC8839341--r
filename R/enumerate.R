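# Combinatorial enumeration of linear and cyclic oligomer compositions.
# Compositions are multisets of monomer counts, not sequences: positional
# isomers and isobaric acid isomers share one composition per count vector
# and topology, mirroring how co-eluting isomers are reported in practice.

#' Parse a composition string
#'
#' Composition strings follow the field's shorthand, e.g. `"2PA+2NPG"` for
#' two phthalic-type acid units and two neopentyl glycol units.
#'
#' @param text A single composition string (`count` prefixes optional,
#'   terms joined by `+`).
#' @return A named integer vector monomer-id -> count.
#' @examples
#' parse_composition("2PA+NPG+HD")
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  terms <- stringr::str_split(gsub("\\s", "", text), "\\+")[[1]]
  m <- stringr::str_match(terms, "^([0-9]*)([A-Za-z][A-Za-z0-9]*)$")
  if (anyNA(m[, 1L])) stop("malformed composition string: ", text, call. = FALSE)
  counts <- ifelse(nzchar(m[, 2L]), as.integer(m[, 2L]), 1L)
  tapply(counts, m[, 3L], sum) |>
    (\(x) stats::setNames(as.integer(x), names(x)))()
}

#' Canonical composition string
#'
#' @param counts Named integer vector monomer-id -> count (count >= 1).
#' @param library A `monomer_library`; ordering follows library row order
#'   (acids before polyols in the default library, matching the reporting
#'   convention).
#' @return A single string such as `"2PA+NPG+HD"`.
#' @export
composition_string <- function(counts, library = default_monomer_library()) {
  counts <- counts[counts > 0L]
  ord <- order(match(names(counts), library$id), names(counts))
  counts <- counts[ord]
  paste0(ifelse(counts == 1L, "", counts), names(counts), collapse = "+")
}

count_classes <- function(counts, library) {
  cls <- library$monomer_class[match(names(counts), library$id)]
  if (anyNA(cls)) {
    stop("unknown monomer id(s): ",
         paste(names(counts)[is.na(cls)], collapse = ", "), call. = FALSE)
  }
  vapply(split(as.integer(counts), factor(cls, levels = .CLASS_FUNCTIONALITY$monomer_class)),
         sum, integer(1))
}

#' Ester-bond count of a composition
#'
#' A linear chain of u units holds u − 1 ester bonds; ring closure adds one
#' more, so the fully cyclised form holds u. Each bond costs one water.
#'
#' @param composition Named count vector or composition string.
#' @param topology `"linear"` or `"cyclic"`.
#' @return Integer bond count.
#' @examples
#' ester_bond_count("2PA+2NPG", "cyclic")  # 4
#' @export
ester_bond_count <- function(composition, topology = c("linear", "cyclic")) {
  topology <- match.arg(topology)
  if (is.character(composition) && is.null(names(composition))) {
    composition <- parse_composition(composition)
  }
  n_units <- sum(composition)
  if (n_units < 1L) stop("composition must contain at least one unit", call. = FALSE)
  if (topology == "linear") n_units - 1L else n_units
}

#' Chemical feasibility of a composition
#'
#' Encodes the alternating-ester connectivity rules:
#' * cyclic: every unit difunctional (diacid / diol / hydroxyacid), and the
#'   diacid and diol unit counts equal once hydroxyacids (which can close a
#'   ring on their own) are set aside;
#' * linear: acid and alcohol units alternate, so the polyacid and polyol
#'   counts differ by at most one; hydroxyacids insert anywhere; monools
#'   can only cap chain ends (at most two, and only on an acid-bearing
#'   chain);
#' * any tri-functional unit (triacid/triol) forces linear topology —
#'   branched rings are excluded as under-determined.
#'
#' @inheritParams ester_bond_count
#' @param library A `monomer_library`.
#' @return `TRUE` or `FALSE`, with a `reason` attribute explaining a
#'   failure.
#' @examples
#' is_feasible("2PA+2NPG", "cyclic")
#' is_feasible("2PA+NPG", "cyclic")   # acid/diol imbalance
#' @export
is_feasible <- function(composition, topology = c("linear", "cyclic"),
                        library = default_monomer_library()) {
  topology <- match.arg(topology)
  if (is.character(composition) && is.null(names(composition))) {
    composition <- parse_composition(composition)
  }
  composition <- composition[composition > 0L]
  if (sum(composition) < 1L) {
    return(structure(FALSE, reason = "no units"))
  }
  k <- count_classes(composition, library)
  if (topology == "cyclic") {
    if (k[["triacid"]] + k[["triol"]] + k[["monool"]] > 0L) {
      return(structure(FALSE, reason = "ring with non-difunctional unit"))
    }
    if (k[["diacid"]] != k[["diol"]]) {
      return(structure(FALSE, reason = "acid/diol imbalance in ring"))
    }
    return(structure(TRUE, reason = "alternating ring"))
  }
  n_acid <- k[["diacid"]] + k[["triacid"]]
  n_ol <- k[["diol"]] + k[["triol"]]
  if (abs(n_acid - n_ol) > 1L) {
    return(structure(FALSE, reason = "acid/alcohol imbalance in chain"))
  }
  if (k[["monool"]] > 2L) {
    return(structure(FALSE, reason = "more than two chain-end monools"))
  }
  if (k[["monool"]] > 0L && n_acid == 0L) {
    return(structure(FALSE, reason = "monool cap without an acid unit"))
  }
  structure(TRUE, reason = "alternating chain")
}

#' Neutral mass and formula of an oligomer composition
#'
#' `neutral_mass()` is the sum of the monomer monoisotopic masses minus one
#' water per ester bond; `oligomer_formula()` is the matching elemental
#' formula.
#'
#' @inheritParams is_feasible
#' @return `neutral_mass()`: mass in Da; `oligomer_formula()`: an
#'   `elemental_formula`.
#' @examples
#' neutral_mass("2PA+2NPG", "cyclic")                      # 468.1784
#' format_formula(oligomer_formula("2TPA+2NPG", "cyclic")) # "C26H28O8"
#' @export
neutral_mass <- function(composition, topology = c("linear", "cyclic"),
                         library = default_monomer_library()) {
  topology <- match.arg(topology)
  if (is.character(composition) && is.null(names(composition))) {
    composition <- parse_composition(composition)
  }
  idx <- match(names(composition), library$id)
  if (anyNA(idx)) {
    stop("unknown monomer id(s): ",
         paste(names(composition)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(library$mass[idx] * as.numeric(composition)) -
    ester_bond_count(composition, topology) * water_mass()
}

#' @rdname neutral_mass
#' @export
oligomer_formula <- function(composition, topology = c("linear", "cyclic"),
                             library = default_monomer_library()) {
  topology <- match.arg(topology)
  if (is.character(composition) && is.null(names(composition))) {
    composition <- parse_composition(composition)
  }
  idx <- match(names(composition), library$id)
  if (anyNA(idx)) stop("unknown monomer id(s)", call. = FALSE)
  parts <- rep(library$formula[idx], times = as.integer(composition))
  combine_formulas(as.list(parts), ester_bond_count(composition, topology))
}

# Enumerate count multisets over `masses` with size <= max_size and a
# conservative mass bound: net mass = monomer mass - one water (each unit
# loses at least one water in any topology, up to the terminal water that
# the caller's exact filter restores). `companion_penalty` is a lower
# bound on the net mass that max(0, size - 1 - slack) partner units from
# the complementary class must add (alternation rule), used only to prune.
# Returns list(counts = integer matrix, size, mass_sum).
enumerate_multisets <- function(masses, max_size, net_cap,
                                companion_penalty = 0, companion_slack = 0L) {
  n <- length(masses)
  if (n == 0L || max_size == 0L) {
    return(list(counts = matrix(integer(0), nrow = 1L, ncol = n),
                size = 0L, mass_sum = 0))
  }
  net <- masses - water_mass()
  acc_counts <- list()
  bound_ok <- function(size, mass_net) {
    mass_net + max(0L, size - 1L - companion_slack) * companion_penalty <=
      net_cap + 1e-9
  }
  rec <- function(i, counts, size, mass_net) {
    if (!bound_ok(size, mass_net)) return(invisible())
    if (i > n) {
      acc_counts[[length(acc_counts) + 1L]] <<- counts
      return(invisible())
    }
    max_c <- max_size - size
    if (net[i] > 0) max_c <- min(max_c, floor((net_cap - mass_net) / net[i] + 1e-9))
    for (ci in 0:max(0L, max_c)) {
      rec(i + 1L, c(counts, ci), size + ci, mass_net + ci * net[i])
    }
  }
  rec(1L, integer(0), 0L, 0)
  counts <- do.call(rbind, acc_counts)
  keep <- vapply(seq_len(nrow(counts)), function(r) {
    bound_ok(sum(counts[r, ]), sum(counts[r, ] * net))
  }, logical(1))
  counts <- counts[keep, , drop = FALSE]
  list(counts = counts,
       size = as.integer(rowSums(counts)),
       mass_sum = as.numeric(counts %*% masses))
}

#' Enumerate feasible oligomer compositions
#'
#' Generates every chemically feasible linear and cyclic composition from a
#' monomer library, up to a unit count and neutral-mass cutoff. Defaults
#' follow the migrant-screening convention: at most 8 units (homologous
#' series up to n = 8) and 1000 Da (heavier species are not considered
#' toxicologically relevant because they are not absorbed in the gut).
#'
#' Isobaric monomers yield distinct compositions with identical masses.
#' Monool chain caps are off by default (`allow_monools = FALSE`);
#' tri-functional monomers are enumerated as linear (tree) compositions
#' only.
#'
#' @param library A `monomer_library`.
#' @param max_units Maximum total unit count (default 8).
#' @param max_mass Neutral-mass cutoff in Da (default 1000).
#' @param topologies Character subset of `c("cyclic", "linear")`.
#' @param min_units Minimum total unit count (default 1; single monomers
#'   count as 1-unit "oligomers" and carry zero ester bonds).
#' @param allow_monools Admit monool-capped chains (default `FALSE`).
#' @return A tibble sorted by mass then composition string with columns
#'   `composition`, `topology`, `n_units`, `n_ester_bonds`, `formula`,
#'   `mass`.
#' @examples
#' lib <- dplyr::filter(default_monomer_library(), id %in% c("PA", "NPG"))
#' enumerate_oligomers(lib, max_units = 4)
#' @export
enumerate_oligomers <- function(library, max_units = 8L, max_mass = 1000,
                                topologies = c("cyclic", "linear"),
                                min_units = 1L, allow_monools = FALSE) {
  stopifnot(max_units >= 1L, max_mass > 0)
  topologies <- match.arg(topologies, several.ok = TRUE)
  if (nrow(library) == 0L) stop("empty monomer library", call. = FALSE)
  if (!allow_monools) library <- dplyr::filter(library, .data$monomer_class != "monool")

  monool_present <- allow_monools && any(library$monomer_class == "monool")
  slack <- if (monool_present) 3L else 0L
  acid_classes <- c("diacid", "triacid")
  ol_classes <- c("diol", "triol", "monool")
  min_net <- function(classes) {
    m <- library$mass[library$monomer_class %in% classes]
    if (length(m) == 0L) Inf else min(m) - water_mass()
  }
  part <- function(classes, companion_penalty, companion_slack = slack) {
    sub <- library[library$monomer_class %in% classes, , drop = FALSE]
    ms <- enumerate_multisets(sub$mass, max_units, max_mass,
                              companion_penalty, companion_slack)
    ms$ids <- sub$id
    ms$n_tri <- as.integer(ms$counts %*% as.integer(sub$monomer_class %in% c("triacid", "triol")))
    ms
  }
  # each side's sets are pruned by the mass its alternation partners must add
  acids <- part(acid_classes, min_net(ol_classes), companion_slack = 0L)
  ols <- part(ol_classes, min_net(acid_classes))
  has <- part("hydroxyacid", 0)

  n_mono_ol <- if (monool_present) {
    as.integer(ols$counts %*% as.integer(
      library$monomer_class[library$monomer_class %in% ol_classes] == "monool"))
  } else rep(0L, length(ols$size))

  # join acid and polyol multisets on compatible sizes (alternation rule),
  # then cross with hydroxyacid counts; exact filters follow
  a_tbl <- tibble::tibble(a = seq_along(acids$size), sa = acids$size)
  d_tbl <- tibble::tibble(d = seq_along(ols$size), sd = ols$size)
  sp <- tidyr::expand_grid(sa = sort(unique(a_tbl$sa)), sd = sort(unique(d_tbl$sd)))
  sp <- sp[abs(sp$sa - sp$sd) <= 1L + slack, ]
  grid <- a_tbl |>
    dplyr::inner_join(sp, by = "sa", relationship = "many-to-many") |>
    dplyr::inner_join(d_tbl, by = "sd", relationship = "many-to-many")
  grid <- tidyr::expand_grid(grid, h = seq_along(has$size))
  grid$units <- grid$sa + grid$sd + has$size[grid$h]
  grid <- grid[grid$units >= max(1L, min_units) & grid$units <= max_units, ]
  grid$mass_sum <- acids$mass_sum[grid$a] + ols$mass_sum[grid$d] + has$mass_sum[grid$h]

  rows <- list()
  for (topo in topologies) {
    g <- grid
    bonds <- if (topo == "cyclic") g$units else g$units - 1L
    g$mass <- g$mass_sum - bonds * water_mass()
    g <- g[g$mass <= max_mass + 1e-9, ]
    na <- acids$size[g$a]; nd <- ols$size[g$d] - n_mono_ol[g$d]; nmo <- n_mono_ol[g$d]
    tri <- acids$n_tri[g$a] + ols$n_tri[g$d]
    if (topo == "cyclic") {
      keep <- tri == 0L & nmo == 0L & na == nd
    } else {
      keep <- abs(na - nd) <= 1L & nmo <= 2L & !(nmo > 0L & na == 0L)
    }
    g <- g[keep, ]
    if (nrow(g) == 0L) next
    counts <- cbind(acids$counts[g$a, , drop = FALSE],
                    ols$counts[g$d, , drop = FALSE],
                    has$counts[g$h, , drop = FALSE])
    colnames(counts) <- c(acids$ids, ols$ids, has$ids)
    bonds_vec <- as.integer(if (topo == "cyclic") g$units else g$units - 1L)
    rows[[topo]] <- tibble::tibble(
      composition = counts_to_strings(counts, library),
      topology = topo,
      n_units = as.integer(g$units),
      n_ester_bonds = bonds_vec,
      formula = counts_to_formulas(counts, library, bonds_vec),
      mass = g$mass
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(composition = character(), topology = character(),
                          n_units = integer(), n_ester_bonds = integer(),
                          formula = character(), mass = numeric()))
  }
  out |>
    dplyr::select("composition", "topology", "n_units", "n_ester_bonds",
                  "formula", "mass") |>
    dplyr::arrange(.data$mass, .data$composition, .data$topology)
}

# vectorised composition-string construction from a count matrix whose
# columns are monomer ids (library order defines term order)
counts_to_strings <- function(counts, library) {
  ids <- colnames(counts)
  ord <- order(match(ids, library$id), ids)
  counts <- counts[, ord, drop = FALSE]
  ids <- ids[ord]
  cols <- lapply(seq_along(ids), function(j) {
    cj <- counts[, j]
    ifelse(cj > 0L, paste0(ifelse(cj == 1L, "", cj), ids[j]), "")
  })
  raw <- do.call(paste, c(cols, sep = "+"))
  raw <- gsub("\\++", "+", raw)
  gsub("^\\+|\\+$", "", raw)
}

# vectorised Hill formula strings: element counts = counts %*% per-monomer
# element matrix, minus bonds waters
counts_to_formulas <- function(counts, library, n_bonds) {
  ids <- colnames(counts)
  if (length(ids) == 0L || nrow(counts) == 0L) return(character(nrow(counts)))
  parsed <- lapply(library$formula[match(ids, library$id)], parse_formula)
  elements <- unique(unlist(lapply(parsed, names)))
  elements <- union(elements, c("C", "H", "O"))
  M <- vapply(parsed, function(f) {
    v <- stats::setNames(rep(0L, length(elements)), elements)
    v[names(f)] <- as.integer(f)
    v
  }, integer(length(elements)))
  E <- counts %*% t(M)
  colnames(E) <- elements
  E[, "H"] <- E[, "H"] - 2L * n_bonds
  E[, "O"] <- E[, "O"] - n_bonds
  hill <- c(intersect(c("C", "H"), elements), sort(setdiff(elements, c("C", "H"))))
  cols <- lapply(hill, function(el) {
    ce <- E[, el]
    ifelse(ce > 0L, paste0(el, ifelse(ce == 1L, "", ce)), "")
  })
  do.call(paste0, cols)
}
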