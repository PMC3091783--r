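#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC-style plot of a threshold scan
#'
#' Plots 1 - specificity against sensitivity over the threshold grid and
#' marks the chosen (nearest-corner) threshold.
#'
#' @param object A `dister_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dister_scan <- function(object, ...) {
  df <- as_tibble(object)
  chosen <- attr(object, "chosen_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$sp, y = .data$se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = df[df$threshold == chosen, , drop = FALSE],
                        colour = "red", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("Threshold scan (%s)", attr(object, "scheme")),
      subtitle = sprintf("chosen threshold %.2f", chosen)
    )
}

#' TU-length histogram of an operon map
#'
#' @param object An `operon_map`.
#' @param ... Unused.
#' @return A ggplot of the TU-length distribution, with the geometric fit
#'   overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.operon_map <- function(object, ...) {
  fit <- fit_geometric(object)
  ggplot2::ggplot(fit$counts, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
                       linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), shape = 1) +
    ggplot2::labs(
      x = "TU length (genes)", y = "number of TUs",
      title = sprintf("TU-length distribution (%s)", object$replicon_id),
      subtitle = sprintf("geometric fit p = %.3f", fit$p_hat)
    )
}

#' Null distribution of the permutation ANOVA F
#'
#' @param object A `tu_permutation`.
#' @param ... Unused.
#' @return A ggplot: histogram of simulated F values with the observed F
#'   marked.
#' @exportS3Method ggplot2::autoplot
autoplot.tu_permutation <- function(object, ...) {
  df <- tidy(object)
  obs <- min(object$observed_f, max(df$f) * 1.5)  # keep Inf plottable
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = obs, colour = "red") +
    ggplot2::labs(
      x = "simulated F", y = "count",
      title = "TU-label permutation null",
      subtitle = sprintf("observed F = %.2f, p = %.4g (%d permutations)",
                         object$observed_f, object$p_value, object$n_perm)
    )
}

#' Intergenic-distance distributions by pair orientation
#'
#' @param pairs A feature-complete pair tibble.
#' @param max_distance Truncate the x-axis (default 400 bp).
#' @return A ggplot of per-orientation distance densities.
#' @export
plot_intergenic_distances <- function(pairs, max_distance = 400) {
  df <- filter(pairs, .data$distance <= max_distance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance,
                                   colour = .data$orientation)) +
    ggplot2::geom_freqpoly(binwidth = 10) +
    ggplot2::geom_vline(xintercept = c(-20, 30), linetype = "dotted") +
    ggplot2::labs(x = "intergenic distance (bp)", y = "pairs",
                  colour = NULL,
                  title = "Intergenic distances by orientation")
}
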