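#' Plot an electrophysiological trace
#'
#' @param trace An `ephys_trace`.
#' @param events Optional event tibble with `onset` / `end` columns (e.g.
#'   from [detect_gdps()]) shaded behind the trace.
#'
#' @return A ggplot.
#' @export
plot_trace <- function(trace, events = NULL) {
  assert_trace(trace)
  ylab <- if (trace_mode(trace) == "current_clamp") "membrane potential (mV)" else "current (pA)"
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_ms / 1000, y = .data$value))
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$onset / 1000, xmax = .data$end / 1000,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the time courses of a simulated network event
#'
#' Facets the somatic potential and the mean dendritic Cl-/HCO3-
#' concentrations against time.
#'
#' @param object A `gdp_simulation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gdp_simulation <- function(object, ...) {
  labs <- c(v_soma = "V soma (mV)", cl_dend = "[Cl-]i dend (mM)",
            hco3_dend = "[HCO3-]i dend (mM)")
  d <- tidy(object)
  d$variable <- factor(d$variable, levels = names(labs), labels = labs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms / 1000, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y",
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("network event at [Cl-]i = %g mM", object$cl_init)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.placement = "outside")
}

#' Plot a cable simulation result
#'
#' @param object A `cable_sim` from [simulate_cable()].
#' @param vars Variables to facet (default: somatic potential and clamp
#'   current).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cable_sim <- function(object, vars = c("v_soma", "i_clamp"), ...) {
  d <- tidy(object)
  d <- d[d$variable %in% vars, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a morphology projection
#'
#' 2D (x, y) projection of a morphology with coordinates, line width
#' proportional to diameter.
#'
#' @param morph A [morphology()] with coordinate columns.
#' @return A ggplot.
#' @export
plot_morphology <- function(morph) {
  if (!all(c("x0", "x1") %in% names(morph))) {
    abort("morphology has no coordinates", class = "chloridyn_invalid_parameter")
  }
  d <- morph[morph$region == "dendrite", ]
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linewidth = .data$diam_prox)) +
    ggplot2::geom_point(
      data = morph[morph$region == "soma", ],
      ggplot2::aes(x = .data$x0, y = .data$y0, size = .data$diam_prox),
      shape = 21, fill = "grey70"
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::scale_size(guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
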