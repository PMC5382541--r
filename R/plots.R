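.LAYER_COLOURS <- c(green2d = "grey40", grass = "#d8b341",
                    shrub = "#3c78b4", tree = "#2e8540")

#' Plot functional connectivity curves
#'
#' CI against dispersal distance for each layer, with a dotted reference
#' line at the high-connectivity threshold.
#'
#' @param curves Named list of [connectivity_curve()]s (NULL entries are
#'   dropped).
#' @param ci_threshold Reference CI level (default 0.15).
#' @return A ggplot object.
#' @export
plot_connectivity_curves <- function(curves, ci_threshold = 0.15) {
  df <- do.call(rbind, lapply(Filter(Negate(is.null), curves), as.data.frame))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_m, .data$ci,
                                   colour = .data$layer)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = ci_threshold, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = .LAYER_COLOURS) +
    ggplot2::labs(x = "dispersal distance (m)", y = "connectivity index",
                  colour = "layer") +
    ggplot2::theme_minimal()
}

#' Plot 2D-versus-stratum bias curves
#'
#' The CI difference between each stratum and the 2D green cover against
#' dispersal distance.
#'
#' @param bias Named list of [bias_curve()]s (NULL entries are dropped).
#' @return A ggplot object.
#' @export
plot_bias_curves <- function(bias) {
  df <- do.call(rbind, lapply(Filter(Negate(is.null), bias), as.data.frame))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_m, .data$delta_ci,
                                   colour = .data$layer)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = .LAYER_COLOURS) +
    ggplot2::labs(x = "dispersal distance (m)",
                  y = "CI difference (stratum - 2D)", colour = "stratum") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
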