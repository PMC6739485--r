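# ggplot2 displays for the main result types. Visualisation is a
# convenience layer; all quantitative output is available as tibbles.

#' Heatmap of a clone-size histogram or residual map
#'
#' Frequency histograms are drawn on a sequential scale; residual maps
#' on a diverging scale centred at zero. The geometric median of the
#' summarised clones can be overlaid when supplied.
#'
#' @param object A `clone_histogram`.
#' @param median_point Optional one-row tibble from
#'   [geometric_median()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clone_histogram <- function(object, median_point = NULL, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$m, y = .data$n, fill = .data$f)) +
    geom_tile() +
    labs(x = "basal cells per clone (m)",
         y = "suprabasal cells per clone (n)",
         fill = if (object$type == "residual") "difference" else "frequency") +
    theme_minimal()
  p <- if (object$type == "residual") {
    p + scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b")
  } else {
    p + scale_fill_viridis_c()
  }
  if (!is.null(median_point)) {
    p <- p + geom_point(data = median_point,
                        aes(x = .data$m, y = .data$n), inherit.aes = FALSE,
                        colour = "black", size = 2)
  }
  p
}

#' Profile likelihood of a tilt fit
#'
#' @param object A `tilt_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the profile with the estimate and
#'   confidence bounds.
#' @export
autoplot.tilt_fit <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$delta, y = .data$loglik)) +
    geom_line() +
    geom_vline(xintercept = object$estimate, linetype = 2) +
    geom_vline(xintercept = c(object$conf.low, object$conf.high),
               linetype = 3) +
    labs(x = "fate tilt delta", y = "profile log-likelihood") +
    theme_minimal()
}

#' Basal-density trajectory of a simulated experiment
#'
#' @param experiment A `clone_experiment` or `tissue_sim`.
#' @return A ggplot of relative basal density over time (per animal for
#'   experiments).
#' @export
plot_density_trajectory <- function(experiment) {
  dens <- if (inherits(experiment, "clone_experiment")) experiment$density
          else experiment$density
  p <- ggplot(dens, aes(x = .data$time_h / 24, y = .data$rel_density))
  if ("animal_id" %in% names(dens)) {
    p <- p + geom_line(aes(group = .data$animal_id), alpha = 0.6)
  } else {
    p <- p + geom_line()
  }
  p + geom_hline(yintercept = 1, linetype = 3) +
    labs(x = "time (days)", y = "basal density relative to homeostasis") +
    theme_minimal()
}
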