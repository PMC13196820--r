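#' Plot a group difference map
#'
#' Per-index signed outward displacement with a 3-standard-error band;
#' negative values indicate inward displacement (atrophy).
#'
#' @param object a [group_mean_difference()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.group_difference_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$point, y = .data$signed)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$signed - 3 * .data$se_signed,
                                      ymax = .data$signed + 3 * .data$se_signed),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(x = "correspondence index",
                  y = "signed outward displacement",
                  title = "Per-index group mean difference (negative = atrophy)") +
    ggplot2::theme_minimal()
}

#' Plot a metric report
#'
#' One panel per metric, one bar per underlying distance.
#'
#' @param object an [evaluate_generation()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tibble::tibble(
    distance = rep(object$distance, 3L),
    metric = rep(c("MMD", "coverage", "density"), each = nrow(object)),
    value = c(object$mmd, object$coverage, object$density)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$value)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Generation metrics") +
    ggplot2::theme_minimal()
}

#' Scatter a shape population coloured by correspondence
#'
#' Projects points onto two chosen axes and colours them by the
#' [correspondence_colormap()] of a reference shape, so preserved
#' correspondence appears as a coherent colour pattern across shapes.
#'
#' @param data a `shape_dataset` (a small subset plots best) or `point_set`.
#' @param reference reference shape for the colour map; defaults to the mean
#'   of `data`.
#' @param axes which coordinates to plot, e.g. `c("x", "z")`.
#' @return a ggplot.
#' @export
plot_correspondence <- function(data, reference = NULL, axes = c("x", "y")) {
  if (is_point_set(data)) data <- shape_dataset(list(data))
  if (is.null(reference)) reference <- mean_shape(data)
  cm <- correspondence_colormap(reference)
  df <- as_tibble_shapes(data)
  df$hex <- cm$hex[df$point]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]])) +
    ggplot2::geom_point(colour = df$hex, size = 1) +
    ggplot2::facet_wrap(~id) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Correspondence colour map") +
    ggplot2::theme_minimal()
}

#' Plot a diffusion training curve
#'
#' @param object a trained [noise_predictor()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.noise_predictor <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "epoch", y = "mean ε-prediction loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
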