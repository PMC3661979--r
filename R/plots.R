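#' Replicate Z-score scatter plot with the dual hit thresholds
#'
#' @param hits Output of [call_hits()] (columns `z1`, `z2`,
#'   `screen_positive`).
#' @param z_hi,z_lo Thresholds drawn as guide lines.
#' @return A ggplot.
#' @export
plot_screen_scatter <- function(hits, z_hi = 3, z_lo = 2.5) {
  assert_columns(hits, c("z1", "z2", "screen_positive"), "`hits`")
  ggplot2::ggplot(hits, ggplot2::aes(.data$z1, .data$z2,
                                     colour = .data$screen_positive)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(z_lo, z_hi), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(z_lo, z_hi), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "Z (replicate 1)", y = "Z (replicate 2)",
                  colour = "screen positive") +
    ggplot2::theme_classic()
}

#' Distribution of distances to the nearest peak of other factors
#'
#' @param nearest Output of [nearest_factor_distance()].
#' @return A ggplot (log10-spaced histogram of distances).
#' @export
plot_nearest_distances <- function(nearest) {
  assert_columns(nearest, "nearest_distance", "`nearest`")
  ggplot2::ggplot(dplyr::filter(nearest, !is.na(.data$nearest_distance)),
                  ggplot2::aes(.data$nearest_distance + 1)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance to nearest other-factor summit + 1 (bp)",
                  y = "peaks") +
    ggplot2::theme_classic()
}
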