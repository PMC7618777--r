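# ggplot2 figures for each result type.

#' Positional-fidelity bar plot
#'
#' @param object A `fidelity_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fidelity_profile <- function(object, ...) {
  ggplot2::ggplot(object$positional, ggplot2::aes(.data$position, .data$fidelity)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_hline(
      yintercept = object$average_fidelity,
      linetype = "dashed", colour = "grey30"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "product position", y = "positional fidelity",
      title = sprintf(
        "average per-nucleotide fidelity %.1f%% (%s mean)",
        100 * object$average_fidelity, object$method
      )
    ) +
    ggplot2::theme_minimal()
}

#' Time course with its exponential fit
#'
#' @param object An `exp_fit`.
#' @param tc The time-course tibble the fit was made on.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.exp_fit <- function(object, tc = NULL, ...) {
  if (is.null(tc)) {
    env <- environment(stats::formula(object$fit))
    tc <- tibble::tibble(time = env$t, y = env$y)
  }
  grid <- tibble::tibble(time = seq(0, max(tc$time), length.out = 200))
  grid$y <- object$A * (1 - exp(-object$k * grid$time))
  ggplot2::ggplot(tc, ggplot2::aes(.data$time, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "time (min)", y = "fraction cleaved",
      title = sprintf(
        "A = %.3f, k = %.4f /min, initial rate %.4f /min, R² = %.4f",
        object$A, object$k, object$initial_rate, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Double-mutant fitness heatmap
#'
#' First constituent mutation on the x axis, second on the y axis, mean
#' fitness as fill; unmeasured combinations are simply absent (grey
#' background).
#'
#' @param table A `fitness_table`.
#' @return A ggplot.
#' @export
plot_fitness_heatmap <- function(table) {
  hm <- fitness_heatmap_data(table)
  ggplot2::ggplot(hm, ggplot2::aes(.data$mutation_1, .data$mutation_2,
    fill = .data$f_mean
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "fitness") +
    ggplot2::labs(x = "first mutation", y = "second mutation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank(),
      panel.background = ggplot2::element_rect(fill = "grey85", colour = NA)
    )
}

#' Active fraction versus copying fidelity
#'
#' @param sweep Tibble from [qs_sweep()].
#' @return A ggplot.
#' @export
plot_qs_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$q, .data$active_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "per-nucleotide copying fidelity q",
      y = "active-variant fraction at mutation-selection balance"
    ) +
    ggplot2::theme_minimal()
}
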