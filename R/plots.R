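#' Plot a simulated plasmid-dynamics trajectory
#'
#' Population densities over time on a log scale, one line per population;
#' densities of exactly zero are omitted (they have no log).
#'
#' @param object a `plasmid_trajectory` from [simulate_plasmid_dynamics()].
#' @param populations which populations to draw (default all six).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.plasmid_trajectory <- function(object,
                                        populations = c(
                                          "CP", "CN", "D1", "D2", "T1", "T2"
                                        ),
                                        ...) {
  long <- object |>
    tidyr::pivot_longer(
      dplyr::all_of(populations),
      names_to = "population", values_to = "density"
    ) |>
    filter(.data$density > 0)
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$time, .data$density, colour = .data$population)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (h)", y = "density (cfu/ml)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot ensemble final densities
#'
#' Mean final density per population with one-standard-deviation error
#' bars across runs.
#'
#' @param object a `plasmid_ensemble` from [run_ensemble()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.plasmid_ensemble <- function(object, ...) {
  s <- filter(object$summary, .data$population != "R_res")
  ggplot2::ggplot(s, ggplot2::aes(.data$population, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$mean - .data$sd, 0),
        ymax = .data$mean + .data$sd
      ),
      width = 0.25
    ) +
    ggplot2::labs(
      x = NULL, y = "final density (cfu/ml)",
      title = paste0("Ensemble of ", object$n_runs, " runs")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a competition fit
#'
#' Observed plasmid-bearing frequencies per transfer with the fitted
#' logit-linear trajectory overlaid.
#'
#' @param object a `selection_fit` from [estimate_s()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.selection_fit <- function(object, ...) {
  obs <- object$data
  fitted0 <- plogis(coef(object$lm_fit)[1])
  curve <- predict_frequency(
    fitted0, object$s_hat, max(obs$transfer), object$gens_per_transfer
  )
  ggplot2::ggplot(obs, ggplot2::aes(.data$transfer, .data$q)) +
    ggplot2::geom_line(
      data = curve, colour = "grey40", linetype = "dashed"
    ) +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "transfer", y = "plasmid-bearing frequency q",
      title = sprintf(
        "s = %.3f per generation (%s)", object$s_hat, object$classification
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mutation spectrum
#'
#' Bar chart of isolate counts per escape-mutation category.
#'
#' @param tally output of [tally_spectrum()].
#' @return a ggplot object.
#' @export
plot_spectrum <- function(tally) {
  assert_columns(tally, c("category", "n"))
  ggplot2::ggplot(
    tally,
    ggplot2::aes(stats::reorder(.data$category, .data$n), .data$n)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "isolates") +
    ggplot2::theme_minimal()
}
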