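#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   facet_grid labs theme_minimal vars geom_abline
NULL

#' @export
ggplot2::autoplot

#' Plot a pollutant panel
#'
#' Daily concentrations, one facet per channel (free y scales; CO is in
#' mg/m3, the rest in ug/m3).
#'
#' @param object A `pollutant_panel` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pollutant_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"date",
                              names_to = "pollutant", values_to = "value")
  long$pollutant <- factor(long$pollutant, levels = POLLUTANTS)
  ggplot(long, aes(x = .data$date, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$pollutant), scales = "free_y", ncol = 2) +
    labs(x = NULL, y = "concentration") +
    theme_minimal()
}

#' Plot an IMF decomposition
#'
#' One facet per component, highest frequency first, residue last.
#'
#' @param object An `imf_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imf_set <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$t, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_grid(rows = vars(.data$component), scales = "free_y") +
    labs(x = "time index", y = NULL) +
    theme_minimal()
}

#' Plot observed versus forecast concentrations
#'
#' @param object A `forecast_result`.
#' @param kind `"series"` for the two curves over the test period,
#'   `"scatter"` for predicted against observed with the identity line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.forecast_result <- function(object, kind = c("series", "scatter"),
                                     ...) {
  kind <- arg_match(kind)
  td <- tidy(object)
  if (kind == "series") {
    long <- tidyr::pivot_longer(td, c("y_true", "y_pred"),
                                names_to = "series", values_to = "value")
    ggplot(long, aes(x = .data$date, y = .data$value,
                     colour = .data$series)) +
      geom_line(linewidth = 0.4) +
      labs(x = NULL, y = object$target, colour = NULL) +
      theme_minimal()
  } else {
    ggplot(td, aes(x = .data$y_true, y = .data$y_pred)) +
      geom_point(alpha = 0.5, size = 0.8) +
      geom_abline(slope = 1, intercept = 0, linetype = 2) +
      labs(x = "observed", y = "predicted") +
      theme_minimal()
  }
}

#' Plot swarm convergence
#'
#' Global-best fitness per iteration (monotone non-increasing).
#'
#' @param object A `pso_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pso_result <- function(object, ...) {
  ggplot(object$history, aes(x = .data$iteration, y = .data$best_fitness)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "iteration", y = "best fitness") +
    theme_minimal()
}
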