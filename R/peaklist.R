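# Centroided peak lists: a tibble (mz, intensity) carrying the instrument
# tag and its default tolerance model as attributes.

.INSTRUMENTS <- list(
  maldi_tof = list(window = c(350, 4000), tol = list(value = 10, unit = "ppm")),
  ion_trap  = list(window = c(100, 1000), tol = list(value = 0.3, unit = "da"))
)

#' Build a centroided peak list
#'
#' @param mz Numeric m/z values (any order; stored sorted ascending).
#' @param intensity Non-negative intensities (default all 1).
#' @param instrument `"maldi_tof"` (window m/z 350-4000, default tolerance
#'   10 ppm reflecting reflector-mode external calibration) or
#'   `"ion_trap"` (window m/z 100-1000, default tolerance 0.3 Da for a
#'   unit-resolution trap).
#' @param tol,tol_unit Optional tolerance override; `tol_unit` is `"ppm"`
#'   or `"da"`.
#' @return A tibble of class `peaklist` with columns `mz`, `intensity`,
#'   and attributes `instrument` and `tolerance`.
#' @examples
#' peaklist(c(491.17, 505.19), c(100, 40), instrument = "ion_trap")
#' @export
peaklist <- function(mz, intensity = NULL, instrument = c("maldi_tof", "ion_trap"),
                     tol = NULL, tol_unit = c("ppm", "da")) {
  instrument <- match.arg(instrument)
  mz <- suppressWarnings(as.numeric(mz))
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  intensity <- suppressWarnings(as.numeric(intensity))
  stopifnot(length(mz) == length(intensity))
  if (anyNA(mz)) stop("malformed or NA m/z values", call. = FALSE)
  if (anyNA(intensity) || any(intensity < 0)) {
    stop("negative or malformed intensities are not allowed", call. = FALSE)
  }
  win <- .INSTRUMENTS[[instrument]]$window
  if (length(mz) > 0L && (min(mz) < win[1] || max(mz) > win[2])) {
    warning("peak(s) outside the ", instrument, " window [", win[1], ", ",
            win[2], "] m/z", call. = FALSE)
  }
  tolerance <- if (is.null(tol)) {
    .INSTRUMENTS[[instrument]]$tol
  } else {
    list(value = tol, unit = match.arg(tol_unit))
  }
  ord <- order(mz)
  out <- tibble::tibble(mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord]))
  structure(out, class = c("peaklist", class(out)),
            instrument = instrument, tolerance = tolerance)
}

#' @export
print.peaklist <- function(x, ...) {
  tolr <- attr(x, "tolerance")
  cat("<peaklist> ", nrow(x), " peaks, instrument ", attr(x, "instrument"),
      ", tolerance ", tolr$value, " ", tolr$unit, "\n", sep = "")
  NextMethod()
}

# per-peak tolerance in Da
tolerance_da <- function(mz, tolerance) {
  if (tolerance$unit == "ppm") mz * tolerance$value * 1e-6 else
    rep(tolerance$value, length(mz))
}

peak_tolerance <- function(peaks, tol = NULL, tol_unit = c("da", "ppm")) {
  if (!is.null(tol)) return(list(value = tol, unit = match.arg(tol_unit)))
  tolr <- attr(peaks, "tolerance")
  if (is.null(tolr)) list(value = 0.3, unit = "da") else tolr
}

#' Read a peak list from CSV or MGF
#'
#' CSV is the primary dialect: a header row, columns `mz` and `intensity`
#' (comma-separated, dot decimal; `#` comment lines skipped). A file with
#' only an m/z column is accepted with intensities defaulting to 1 and a
#' warning. MGF files must contain at least one `BEGIN IONS` block; the
#' first block is read and its header lines (TITLE, PEPMASS, ...) are kept
#' as a `metadata` attribute.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @inheritParams peaklist
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "mgf"),
                          instrument = c("maldi_tof", "ion_trap"),
                          tol = NULL, tol_unit = c("ppm", "da")) {
  format <- match.arg(format)
  instrument <- match.arg(instrument)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
    if (nrow(readr::problems(df)) > 0L) {
      p <- readr::problems(df)
      stop("malformed peak-list row(s) at line(s): ",
           paste(utils::head(p$row, 5L), collapse = ", "), call. = FALSE)
    }
    names(df) <- tolower(names(df))
    if (!"mz" %in% names(df)) {
      if (ncol(df) >= 1L) names(df)[1L] <- "mz" else
        stop("peak-list CSV has no columns", call. = FALSE)
    }
    if (!"intensity" %in% names(df)) {
      if (ncol(df) >= 2L) {
        names(df)[2L] <- "intensity"
      } else {
        warning("no intensity column; defaulting intensities to 1", call. = FALSE)
        df$intensity <- 1
      }
    }
    return(peaklist(df$mz, df$intensity, instrument, tol, tol_unit))
  }
  lines <- readr::read_lines(path)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) == 0L || length(end) == 0L) {
    stop("no BEGIN IONS block found in ", path, call. = FALSE)
  }
  block <- lines[(begin[1L] + 1L):(end[1L] - 1L)]
  is_header <- grepl("=", block, fixed = TRUE)
  meta <- block[is_header]
  rows <- block[!is_header & nzchar(trimws(block))]
  parts <- stringr::str_split_fixed(trimws(rows), "[ \t]+", 2L)
  mz <- suppressWarnings(as.numeric(parts[, 1L]))
  intens <- suppressWarnings(as.numeric(parts[, 2L]))
  if (anyNA(mz)) {
    stop("malformed MGF peak row(s): ",
         paste(utils::head(which(is.na(mz)), 5L), collapse = ", "), call. = FALSE)
  }
  intens[is.na(intens)] <- 1
  out <- peaklist(mz, intens, instrument, tol, tol_unit)
  attr(out, "metadata") <- stats::setNames(
    sub("^[^=]*=", "", meta), sub("=.*$", "", meta)
  )
  out
}

#' Write a peak list to CSV or MGF
#'
#' CSV output carries a provenance comment header (package version and,
#' when supplied, the generator seed). Values are written with six decimal
#' places so write/read round-trips are exact at that precision.
#'
#' @param peaks A [peaklist()] or tibble with `mz` and `intensity`.
#' @param path Output path; format chosen by extension (`.mgf` or CSV).
#' @param seed Optional seed recorded in the provenance header.
#' @param title MGF TITLE line (MGF output only).
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path, seed = NULL, title = "polyestermz export") {
  if (grepl("\\.mgf$", path, ignore.case = TRUE)) {
    body <- sprintf("%.6f %.6f", peaks$mz, peaks$intensity)
    readr::write_lines(
      c("BEGIN IONS", paste0("TITLE=", title), body, "END IONS"), path
    )
    return(invisible(path))
  }
  header <- c(
    paste0("# polyestermz ", as.character(utils::packageVersion("polyestermz"))),
    if (!is.null(seed)) paste0("# seed=", seed),
    paste0("# instrument=", attr(peaks, "instrument") %||% "unknown")
  )
  readr::write_lines(header, path)
  readr::write_csv(
    tibble::tibble(mz = round(peaks$mz, 6), intensity = round(peaks$intensity, 6)),
    path, append = TRUE, col_names = TRUE
  )
  invisible(path)
}

#' Write a candidate or report table as CSV with provenance header
#'
#' @param tbl A tibble (candidate database, annotation report, series
#'   table, safety table).
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(tbl, path, seed = NULL) {
  header <- c(
    paste0("# polyestermz ", as.character(utils::packageVersion("polyestermz"))),
    if (!is.null(seed)) paste0("# seed=", seed)
  )
  num <- vapply(tbl, is.numeric, logical(1))
  tbl[num] <- lapply(tbl[num], function(x) round(x, 6))
  readr::write_lines(header, path)
  readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
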