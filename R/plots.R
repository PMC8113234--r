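# Diagnostic ggplot2 figures for the result objects.

#' @rdname run_dynamics
#' @param object An `evo_dynamics` object.
#' @param ... Unused.
#' @method autoplot evo_dynamics
#' @export
autoplot.evo_dynamics <- function(object, ...) {
  d <- object$summary |>
    dplyr::mutate(size_class = sprintf("%d species", .data$n_species))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75,
                   fill = .data$size_class), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median,
                                    color = .data$size_class)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "generation", y = "normalized distance",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replicate variability across generations
#'
#' Median and interquartile ribbon of per-community variability by size
#' class, with per-community dots.
#'
#' @param profile A tibble from [variability_profile()].
#' @return A ggplot object.
#' @export
plot_variability_profile <- function(profile) {
  d <- profile |>
    dplyr::mutate(size_class = sprintf("%d species", .data$n_species))
  s <- d |>
    dplyr::summarise(
      median = median(.data$variability),
      q25 = quantile(.data$variability, 0.25, names = FALSE),
      q75 = quantile(.data$variability, 0.75, names = FALSE),
      .by = c("size_class", "generation"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75,
                   fill = .data$size_class), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median,
                                    color = .data$size_class)) +
    ggplot2::geom_point(
      data = d,
      ggplot2::aes(y = .data$variability, color = .data$size_class),
      alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "generation", y = "variability (distance from medoid)",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname shuffle_null
#' @param object A `shuffle_null` object.
#' @method autoplot shuffle_null
#' @export
autoplot.shuffle_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(null_mean = object$null_means),
                  ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_mean,
                        color = "firebrick") +
    ggplot2::labs(
      x = "mean repeatability score under shuffle null",
      y = "iterations",
      title = sprintf("%d-species class: observed %.3f, p = %.3g",
                      object$n_species, object$observed_mean,
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot mean prediction accuracy by method across generations
#'
#' @param accuracy_summary A tibble from [summarize_accuracy()].
#' @return A ggplot object.
#' @export
plot_accuracy_summary <- function(accuracy_summary) {
  ggplot2::ggplot(
    accuracy_summary,
    ggplot2::aes(x = .data$generation, y = .data$mean_accuracy,
                 color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$se,
                   ymax = .data$mean_accuracy + .data$se),
      size = 0.3) +
    ggplot2::labs(x = "generation", y = "prediction accuracy",
                  color = NULL) +
    ggplot2::theme_minimal()
}
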