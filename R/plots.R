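# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the DEG-count model and its residuals
#'
#' Observed nDEG against the smaller arm size, with the fitted
#' negative-binomial mean curve; clusters far above the curve are the
#' vulnerable candidates.
#'
#' @param object an [fit_ndeg_model()] result.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot ndeg_fit
#' @export
autoplot.ndeg_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, min_cells = pmin(.data$x1, .data$x2))
  grid <- tibble::tibble(min_cells = seq(min(d$min_cells), max(d$min_cells),
                                         length.out = 200))
  grid$mu <- exp(object$intercept + object$b1 * log(grid$min_cells))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$min_cells, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$mu), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cells in smaller arm", y = "nDEG",
                  title = "Differential genes vs. cluster size (NB fit)")
}

#' Plot a cell-type discovery curve
#'
#' Mean detected cell types per subsample size with a ribbon of +/- 1 SD;
#' pass a fitted [fit_michaelis_menten()] to overlay the saturation curve.
#'
#' @param object a [subsample_curve()] tibble.
#' @param fit optional `mm_fit` overlay.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot saturation_curve
#' @export
autoplot.saturation_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$mean_detected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_detected - .data$sd_detected,
                                      ymax = .data$mean_detected + .data$sd_detected),
                         alpha = 0.2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "cells sampled", y = "cell types detected",
                  title = "Cell-type discovery saturation")
  if (!is.null(fit)) {
    grid <- tibble::tibble(size = seq(0, max(object$size), length.out = 300))
    grid$mean_detected <- fit$vmax * grid$size / (fit$km + grid$size)
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}

#' Plot summed signed ranks across genotypes
#'
#' Genes ordered by summed rank, tails highlighted: the left edge holds the
#' commonly upregulated genes, the right edge the commonly downregulated.
#'
#' @param object an [aggregate_ranks()] result.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot convergence_result
#' @export
autoplot.convergence_result <- function(object, ...) {
  d <- dplyr::mutate(object$summed,
                     position = dplyr::row_number(),
                     tail = dplyr::case_when(
                       .data$gene %in% object$common_up ~ "common up",
                       .data$gene %in% object$common_down ~ "common down",
                       TRUE ~ "middle"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$summed_rank,
                                  colour = .data$tail)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "gene (sorted)", y = "summed signed rank",
                  title = "Cross-genotype rank convergence")
}

#' Plot lasso decomposition weights
#'
#' @param object a [lasso_decompose()] result.
#' @param threshold match cutoff drawn as a dashed line.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot decomposition
#' @export
autoplot.decomposition <- function(object, threshold = 0.1, ...) {
  d <- dplyr::arrange(object$weights, .data$weight)
  d$profile <- factor(d$profile, levels = d$profile)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$profile)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "lasso weight", y = NULL,
                  title = "Cluster decomposition over bulk references")
}
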