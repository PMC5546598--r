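# Tidy result containers for the analysis engine.

new_bsp_result <- function(data, axis_kind, axis = names(data)[1], meta = list()) {
  out <- tibble::as_tibble(data)
  attr(out, "axis_kind") <- axis_kind
  attr(out, "axis") <- axis
  attr(out, "meta") <- meta
  class(out) <- c("bsp_result", class(out))
  out
}

#' @export
print.bsp_result <- function(x, ...) {
  cat(sprintf("<bsp_result: %s axis '%s', %d point(s), %d series>\n",
              attr(x, "axis_kind"), attr(x, "axis"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Tidy an engine result into long form
#'
#' @param x a result from [time_course()], [dc_sweep()] or
#'   [transfer_function()].
#' @param ... unused.
#' @return a tibble with columns `<axis>`, `series`, `value`.
#' @method tidy bsp_result
#' @export
tidy.bsp_result <- function(x, ...) {
  axis <- attr(x, "axis")
  tidyr::pivot_longer(tibble::as_tibble(x), -dplyr::all_of(axis),
                      names_to = "series", values_to = "value")
}

#' One-row summary of an engine result
#'
#' @param x a `bsp_result`.
#' @param ... unused.
#' @return a tibble with the axis kind, range and series count.
#' @method glance bsp_result
#' @export
glance.bsp_result <- function(x, ...) {
  axis <- attr(x, "axis")
  tibble::tibble(axis_kind = attr(x, "axis_kind"),
                 axis_min = min(x[[axis]]), axis_max = max(x[[axis]]),
                 n_points = nrow(x), n_series = ncol(x) - 1L)
}

#' Plot an engine result
#'
#' Time courses and DC sweeps are drawn as one line per species;
#' frequency responses as a Bode pair (magnitude in dB, phase in
#' degrees) with a log frequency axis.
#'
#' @param object a `bsp_result`.
#' @param species optional subset of series to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bsp_result
#' @export
autoplot.bsp_result <- function(object, species = NULL, ...) {
  axis <- attr(object, "axis")
  kind <- attr(object, "axis_kind")
  long <- tidy.bsp_result(object)
  if (!is.null(species)) long <- dplyr::filter(long, .data$series %in% species)
  if (kind == "frequency") {
    long <- dplyr::mutate(long,
      value = ifelse(.data$series == "magnitude_db", .data$value, .data$value),
      panel = ifelse(.data$series == "phase_deg", "phase (deg)", "magnitude (dB)"))
    long <- dplyr::filter(long, .data$series %in% c("magnitude_db", "phase_deg"))
    return(ggplot2::ggplot(long, ggplot2::aes(.data[[axis]], .data$value)) +
             ggplot2::geom_line() +
             ggplot2::scale_x_log10() +
             ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
             ggplot2::labs(x = "angular frequency (rad/time)", y = NULL))
  }
  xlab <- if (kind == "time") "time" else "input concentration"
  ggplot2::ggplot(long, ggplot2::aes(.data[[axis]], .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "concentration", colour = "species")
}

#' Write an engine result to CSV
#'
#' One axis column plus one column per species.
#'
#' @param result a `bsp_result`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(tibble::as_tibble(result), path, row.names = FALSE)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
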