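# Monomer registry: named building blocks (polyacids, polyols,
# hydroxyacids) with formulas and functionality, loaded from a CSV config.

.CLASS_FUNCTIONALITY <- tibble::tribble(
  ~monomer_class, ~n_acid_groups, ~n_hydroxyl_groups,
  "diacid",       2L,             0L,
  "triacid",      3L,             0L,
  "diol",         0L,             2L,
  "triol",        0L,             3L,
  "monool",       0L,             1L,
  "hydroxyacid",  1L,             1L
)

#' Load a monomer library from a CSV config file
#'
#' The config has one record per monomer with columns `id`, `abbreviation`,
#' `name`, `formula` (Hill notation of the free monomer), `monomer_class`
#' (one of diacid, triacid, diol, triol, monool, hydroxyacid) and
#' `aromatic` (logical). Lines starting with `#` are comments.
#'
#' @param path Path to the CSV file.
#' @return A tibble of class `monomer_library` with the config columns plus
#'   derived `n_acid_groups`, `n_hydroxyl_groups` and monoisotopic `mass`.
#' @examples
#' lib <- default_monomer_library()
#' dplyr::filter(lib, monomer_class == "diacid")
#' @export
load_monomer_library <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) stop("monomer library file is empty: ", path, call. = FALSE)
  required <- c("id", "abbreviation", "name", "formula", "monomer_class", "aromatic")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("monomer library lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw$aromatic <- as.logical(raw$aromatic)
  validate_monomer_library(raw)
}

#' @rdname load_monomer_library
#' @details `default_monomer_library()` returns the library shipped with the
#'   package: the acid and polyol monomers commonly reported for polyester
#'   food-contact coatings (PA/IPA/TPA, adipic and trimellitic acid; NPG,
#'   EG, DEG, HD, 1,3-/1,4-butanediol, MPO, CHDM, 1,3-propanediol, glycerol,
#'   trimethylolpropane; ring-opened caprolactone). It is an approximation
#'   of the industrial formulary, not an exhaustive list, and is meant to be
#'   extended via a user config.
#' @export
default_monomer_library <- function() {
  path <- system.file("extdata", "monomer_library.csv", package = "polyestermz",
                      mustWork = TRUE)
  load_monomer_library(path)
}

validate_monomer_library <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$abbreviation) > 0L) {
    dups <- unique(df$abbreviation[duplicated(df$abbreviation)])
    stop("duplicate monomer abbreviation(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id) > 0L) stop("duplicate monomer id(s)", call. = FALSE)
  bad_class <- setdiff(unique(df$monomer_class), .CLASS_FUNCTIONALITY$monomer_class)
  if (length(bad_class) > 0L) {
    stop("unknown monomer class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$aromatic)) stop("aromatic flag must be TRUE/FALSE", call. = FALSE)
  df <- dplyr::left_join(df, .CLASS_FUNCTIONALITY, by = "monomer_class")
  df$formula <- vapply(df$formula, function(f) format_formula(parse_formula(f)),
                       character(1))
  df$mass <- monoisotopic_mass(df$formula)
  if (any(df$mass <= 0)) stop("monomer with non-positive mass", call. = FALSE)
  class(df) <- c("monomer_library", class(df))
  df
}

#' Group monomers that share an elemental formula
#'
#' Isobaric monomers (e.g. the phthalic/isophthalic/terephthalic acid
#' isomers, or 1,3-/1,4-butanediol with 2-methyl-1,3-propanediol) cannot be
#' told apart by mass; enumeration keeps them as distinct compositions but
#' series inference and annotation report them as a group.
#'
#' @param library A `monomer_library` tibble.
#' @return A tibble with one row per monomer: `id`, `formula`, `group_id`
#'   (the id of the first member in library order), `group_label`
#'   (members joined by `/`), and `n_in_group`.
#' @examples
#' isobaric_groups(default_monomer_library())
#' @export
isobaric_groups <- function(library) {
  library |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$formula, .data$monomer_class) |>
    dplyr::mutate(
      group_id = .data$id[which.min(.data$.row)],
      group_label = paste(.data$id[order(.data$.row)], collapse = "/"),
      n_in_group = dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::select("id", "formula", "monomer_class", "group_id", "group_label",
                  "n_in_group")
}
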