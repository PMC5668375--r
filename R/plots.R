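#' Plot a single-cell trajectory
#'
#' Line plot of the three state variables (total BCR, bound BCR, survival
#' signal) over culture time; a dashed vertical line marks the death time if
#' the cell dies.
#'
#' @param object A `bcr_trajectory` from [simulate_cell()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcr_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[c("t", "bcr_level", "bcr_bound", "signal_on")],
    -"t", names_to = "variable", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                          colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "level (dimensionless)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  death <- attr(object, "death_time")
  if (!is.na(death)) {
    p <- p + ggplot2::geom_vline(xintercept = death, linetype = "dashed")
  }
  p
}

#' Plot a dose x time viability surface
#'
#' Viability against culture time, one line per antibody dose. The
#' characteristic pattern with the fitted parameters is a viability dip at
#' intermediate doses (occupancy above nothing but below the activation
#' threshold, so tonic signal is lost without compensation) and a rescue at
#' saturating doses.
#'
#' @param object A `bcr_viability` tibble from [dose_time_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcr_viability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time_h, .data$viability,
                               colour = factor(.data$dose_ug_ml),
                               group = factor(.data$dose_ug_ml))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (h)", y = "viability (fraction)",
                  colour = "anti-IgM (ug/ml)") +
    ggplot2::theme_minimal()
}

#' Plot GA convergence
#'
#' Best and population-mean objective per generation for a GA fit.
#'
#' @param object A `bcr_fit` from [ga_optimize()] (or a stage fit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcr_fit <- function(object, ...) {
  trace <- object$details$trace
  if (is.null(trace)) abort("this fit has no generation trace")
  long <- tidyr::pivot_longer(trace, c("best", "mean"),
                              names_to = "statistic", values_to = "objective")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$objective,
                                     linetype = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "objective (SSD)") +
    ggplot2::theme_minimal()
}
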