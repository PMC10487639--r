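#' Plot a bimodal score fit over its histogram
#'
#' @param object a `bimodal_fit` from [fit_bimodal()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.bimodal_fit <- function(object, ...) {
  h <- object$histogram
  if (is.null(h)) {
    x <- seq(object$score_range[1], object$score_range[2], length.out = 200)
    h <- tibble::tibble(center = x, count = NA_real_)
  }
  x <- seq(min(h$center), max(h$center), length.out = 400)
  comp <- tibble::tibble(
    x = rep(x, 3),
    y = c(object$bg_amplitude * exp(-(x - object$bg_mean)^2 / (2 * object$bg_sd^2)),
          object$tp_amplitude * exp(-(x - object$tp_mean)^2 / (2 * object$tp_sd^2)),
          object$bg_amplitude * exp(-(x - object$bg_mean)^2 / (2 * object$bg_sd^2)) +
            object$tp_amplitude * exp(-(x - object$tp_mean)^2 / (2 * object$tp_sd^2))),
    component = rep(c("background", "true positives", "bimodal"), each = length(x)))
  p <- ggplot2::ggplot()
  if (!all(is.na(h$count)))
    p <- p + ggplot2::geom_col(data = h,
                               ggplot2::aes(x = .data$center, y = .data$count),
                               width = object$bin_width, fill = "grey80")
  p +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component)) +
    ggplot2::labs(x = "LCCmax", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity/FDR curve with its RUC point
#'
#' @param object a `tm_roc_curve` from [roc_curve()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.tm_roc_curve <- function(object, ...) {
  best <- ruc_point(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fdr, y = .data$sensitivity)) +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::geom_point(data = best, colour = "forestgreen", size = 3) +
    ggplot2::annotate("text", x = best$fdr, y = best$sensitivity,
                      label = sprintf("  RUC %.3f @ %.3f", best$ruc_value,
                                      best$cutoff),
                      hjust = 0, vjust = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false-discovery rate", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Project a neighbor-density map onto a plane
#'
#' @param object a `neighbor_density`.
#' @param projection `"xy"`, `"xz"` or `"yz"`.
#' @param ... ignored.
#' @return a ggplot raster of the summed probability.
#' @export
autoplot.neighbor_density <- function(object, projection = c("xy", "xz", "yz"),
                                      ...) {
  projection <- match.arg(projection)
  sum_axis <- switch(projection, xy = 3, xz = 2, yz = 1)
  m <- apply(object$histogram, setdiff(1:3, sum_axis), sum)
  half <- (dim(object$histogram)[1] - 1) / 2
  coords <- (seq_len(nrow(m)) - half - 1) * object$hist_voxel
  df <- tibble::tibble(
    a = rep(coords, times = ncol(m)),
    b = rep(coords, each = nrow(m)),
    p = as.vector(m))
  labs <- strsplit(projection, "")[[1]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("%s (Å)", labs[1]), y = sprintf("%s (Å)", labs[2]),
                  fill = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a lamella score-depth profile
#'
#' @param profile tibble from [lamella_profile()].
#' @return a ggplot object.
#' @export
plot_lamella_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$z, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(formula = y ~ x, method = "loess", se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "z (Å, layer-centered)", y = "LCCmax") +
    ggplot2::theme_minimal()
}
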