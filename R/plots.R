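# ggplot2 views of the main result types.

#' Stick-spectrum plot of a peak list
#'
#' @param object A [peaklist()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peaklist
#' @export
autoplot.peaklist <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.4) +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = paste0("Peak list (", attr(object, "instrument"), ")")) +
    ggplot2::theme_minimal()
}

#' Annotated spectrum: assigned vs unassigned peaks
#'
#' @param object An `oligomer_annotation` from [annotate_run()].
#' @param ... Unused.
#' @return A ggplot with assigned peaks coloured and labelled by their
#'   rank-1 composition.
#' @method autoplot oligomer_annotation
#' @export
autoplot.oligomer_annotation <- function(object, ...) {
  pk <- tibble::as_tibble(object$peaks)
  pk$peak_idx <- seq_len(nrow(pk))
  top <- object$matches |>
    dplyr::filter(.data$rank == 1L) |>
    dplyr::select("peak_idx", "composition", "adduct")
  pk <- dplyr::left_join(pk, top, by = "peak_idx") |>
    dplyr::mutate(assigned = !is.na(.data$composition))
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, y = .data$intensity,
                                   colour = .data$assigned)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey60"),
                                 name = "assigned") +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Overlay detected homologous series on a spectrum
#'
#' @param peaks A [peaklist()].
#' @param series A tibble from [detect_series()] or [detect_all_series()].
#' @return A ggplot: the spectrum in grey with series members connected
#'   and coloured by series.
#' @export
plot_series <- function(peaks, series) {
  pk <- tibble::as_tibble(peaks)
  members <- purrr::map_dfr(seq_len(nrow(series)), function(i) {
    tibble::tibble(
      series = paste0(series$unit[i] %||% "", " #", series$series_id[i]),
      mz = series$member_mz[[i]]
    )
  })
  members <- dplyr::left_join(members, pk, by = "mz")
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = members,
                        ggplot2::aes(colour = .data$series), size = 1.8) +
    ggplot2::geom_line(data = members,
                       ggplot2::aes(colour = .data$series), linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "intensity", colour = "series") +
    ggplot2::theme_minimal()
}
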