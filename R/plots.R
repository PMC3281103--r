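#' Plot a senescent-fraction curve
#'
#' Line for the mean fraction with a ribbon for the 95% confidence band.
#'
#' @param object A [fraction_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fraction_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pd)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$s_lower, ymax = .data$s_upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$s_mean), colour = "steelblue") +
    ggplot2::labs(x = "Population doubling", y = "Senescent fraction s(PD)") +
    ggplot2::theme_minimal()
}

#' Plot observed and predicted fluorescence trajectories
#'
#' Observed population means as points, model predictions as lines, one
#' facet per channel.
#'
#' @param observed A series tibble (`channel`, `pd`, `value`).
#' @param predicted Optional series tibble of model predictions.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(observed, predicted = NULL) {
  p <- ggplot2::ggplot(observed, ggplot2::aes(x = .data$pd, y = .data$value)) +
    ggplot2::geom_point(colour = "grey30", size = 1.2) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "Population doubling", y = "Normalised fluorescence") +
    ggplot2::theme_minimal()
  if (!is.null(predicted)) {
    p <- p + ggplot2::geom_line(data = predicted, colour = "firebrick")
  }
  p
}

#' Plot a model-observation comparison
#'
#' Observed against predicted values with the identity line; the Pearson r
#' is shown in the subtitle.
#'
#' @param object A `series_comparison` from [compare_model_to_observed()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.series_comparison <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = "Predicted", y = "Observed",
      subtitle = paste0("Pearson r = ", formatC(object$r, digits = 4, format = "f"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cell step trajectories
#'
#' Step-function phenotype traces over PD for a sample of simulated cells,
#' illustrating the single non-decreasing jump each cell takes at its
#' transition PD.
#'
#' @param object A `cell_population` from [simulate_cells()].
#' @param pd_grid PD grid on which to draw the traces.
#' @param max_cells At most this many cells are drawn (default 100).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_population <- function(object, pd_grid = NULL, max_cells = 100L, ...) {
  if (is.null(pd_grid)) {
    finite <- object$transition_pd[is.finite(object$transition_pd)]
    rng <- if (length(finite) > 0) range(finite) else c(0, 1)
    pd_grid <- seq(rng[1] - 1, rng[2] + 1, length.out = 60)
  }
  keep <- object[seq_len(min(nrow(object), max_cells)), , drop = FALSE]
  class(keep) <- class(object)
  tr <- cell_trace(keep, pd_grid)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$pd, y = .data$phenotype,
                                   group = .data$cell_id)) +
    ggplot2::geom_step(alpha = 0.35, colour = "steelblue") +
    ggplot2::labs(x = "Population doubling", y = "Phenotype (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a step-model mixture density
#'
#' Kernel density of a simulated two-component mixture together with the
#' two state densities, the visual check behind the unimodality analysis.
#'
#' @param dist_P,dist_S [phenotype_dist] objects.
#' @param s Senescent fraction of the mixture (default 0.5).
#' @param n Cells to simulate (default 500).
#' @return A ggplot object.
#' @export
plot_mixture_density <- function(dist_P, dist_S, s = 0.5, n = 500L) {
  mix <- simulate_mixture(dist_P, dist_S, s, n)
  df <- dplyr::bind_rows(
    tibble(value = sample_phenotype(dist_P, n), component = "proliferating"),
    tibble(value = sample_phenotype(dist_S, n), component = "senescent"),
    tibble(value = mix, component = "mixture")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$component)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Phenotype (a.u.)", y = "Density") +
    ggplot2::theme_minimal()
}
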