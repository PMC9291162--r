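#' Plot a simulation result
#'
#' Faceted time courses of net CO2 uptake, stomatal conductance,
#' intercellular CO2, leaf temperature and bundle-sheath leakiness.
#'
#' @param object a `c4_sim` tibble.
#' @param vars variables to facet.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.c4_sim <- function(object, vars = c("A", "gs", "ci", "tleaf", "phi"),
                            ...) {
  d <- tidyr::pivot_longer(object[, c("time_s", vars)],
                           cols = dplyr::all_of(vars),
                           names_to = "variable", values_to = "value")
  d$variable <- factor(d$variable, levels = vars)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.c4_gx <- function(object, ...) {
  vars <- intersect(c("A", "gs", "Ci"), names(object))
  d <- tidyr::pivot_longer(object[, c("time_s", vars)],
                           cols = dplyr::all_of(vars),
                           names_to = "variable", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare regulation scenarios
#'
#' Overlays the induction of A (or leakiness) for several scenario runs.
#'
#' @param sims named list of `c4_sim` objects (names become the legend).
#' @param var `"A"` or `"phi"`.
#' @return a ggplot object.
#' @export
plot_scenarios <- function(sims, var = "A") {
  d <- dplyr::bind_rows(purrr::imap(sims, function(s, nm) {
    tibble(time_s = s$time_s, value = s[[var]], scenario = nm)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value,
                                  colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = var) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
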