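# ggplot2 views of the standard result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box-plot of placement errors against the random baseline
#'
#' @param predicted [error_distribution()] tibble for predicted sites.
#' @param random [error_distribution()] tibble for the random baseline.
#' @return A ggplot object.
#' @export
plot_error_distribution <- function(predicted, random) {
  df <- dplyr::bind_rows(
    mutate(predicted, source = "predicted"),
    mutate(random, source = "random")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$min_dist)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL,
                  y = "minimum distance to a reference water (Å)") +
    ggplot2::theme_minimal()
}

#' Accuracy by classification-confidence bin
#'
#' @param bins A [confidence_bins()] tibble.
#' @return A ggplot object.
#' @export
plot_confidence_bins <- function(bins) {
  ggplot2::ggplot(dplyr::filter(bins, .data$n > 0),
                  ggplot2::aes(x = .data$bin, y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "maximum class probability",
                  y = "fraction correctly classified") +
    ggplot2::theme_minimal()
}

#' Ligand displacement-propensity profile
#'
#' @param profile A [propensity_profile()] tibble.
#' @param group_type Which grouping to draw: atom `"role"` or
#'   `"element"`.
#' @return A ggplot object.
#' @export
plot_propensity_profile <- function(profile, group_type = "role") {
  df <- dplyr::filter(profile, .data$group_type == !!group_type)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$probability,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance from nearest predicted site (Å)",
                  y = "occupancy probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-class distributions of the three site descriptors
#'
#' @param data Labeled feature tibble (e.g. from
#'   [build_classifier_dataset()]).
#' @param class_col Name of the class column.
#' @return A ggplot object (densities faceted by descriptor).
#' @export
plot_score_distributions <- function(data, class_col = "class") {
  long <- tidyr::pivot_longer(
    data, dplyr::any_of(c("energy", "hydrophilicity", "lipophilicity")),
    names_to = "descriptor", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     colour = .data[[class_col]])) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~descriptor, scales = "free") +
    ggplot2::labs(x = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname select_model
#' @param object A `water_energy_fit`.
#' @method autoplot water_energy_fit
#' @export
autoplot.water_energy_fit <- function(object, ...) {
  df <- tibble(
    observed = object$fit$model[[1]],
    fitted = stats::fitted(object$fit)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = "fitted binding energy (kcal/mol)",
                  y = "calculated binding energy (kcal/mol)") +
    ggplot2::theme_minimal()
}
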