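#' Plot scattering and difference curves
#'
#' `plot_curves()` overlays any number of curves (scattering or difference)
#' on a shared q axis; difference curves get a zero reference line.
#'
#' @param ... Named curve tibbles, or a single list of them.
#' @return A ggplot object.
#' @export
plot_curves <- function(...) {
  curves <- list(...)
  if (length(curves) == 1 && is.list(curves[[1]]) && !is.data.frame(curves[[1]])) {
    curves <- curves[[1]]
  }
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("curve_", seq_along(curves))
  }
  long <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    tibble(
      label = nm, q = cv$q,
      value = if ("I" %in% names(cv)) cv$I else cv$dS,
      kind = if ("I" %in% names(cv)) "I(q)" else "dS(q)"
    )
  }))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$q, .data$value, colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "q (nm^-1)", y = unique(long$kind)[1], colour = NULL) +
    ggplot2::theme_minimal()
  if (any(long$kind == "dS(q)")) {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50")
  }
  p
}

#' Heat-map of a bend/twist residual landscape
#'
#' Displays the best-fraction mean residual per (bend change, dihedral
#' change) bin; the landscape minimum is marked with a cross.
#'
#' @param object A `saxs_landscape` from [build_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saxs_landscape <- function(object, ...) {
  occ <- dplyr::filter(as_tibble(object), !is.na(.data$stat))
  mn <- landscape_minimum(object)
  ggplot2::ggplot(occ, ggplot2::aes(.data$bend, .data$dihedral, fill = .data$stat)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = mn, ggplot2::aes(.data$bend, .data$dihedral),
      shape = 4, size = 3, colour = "white", inherit.aes = FALSE
    ) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "bend change (deg)", y = "dihedral change (deg)",
      fill = "mean residual\n(best fraction)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot amplitude traces from a kinetic decomposition
#'
#' Amplitudes of the early and late basis patterns against time (log axis).
#'
#' @param traces Tibble from [decompose_series()].
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  long <- tidyr::pivot_longer(
    traces[c("time", "amp_early", "amp_late")],
    cols = c("amp_early", "amp_late"),
    names_to = "component", values_to = "amplitude"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$amplitude,
    colour = .data$component
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "amplitude", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fit_halftime
#' @param object A `halftime_fit`.
#' @param ... Unused.
#' @export
autoplot.halftime_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "time (s)", y = "amplitude",
      title = sprintf(
        "%s fit: t_half = %.3g s", object$model, object$t_half
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
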