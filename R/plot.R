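#' Plot a viewpoint profile
#'
#' Smoothed (or normalized) signal along the chromosome, with the viewpoint
#' marked and masked fragments omitted; optionally overlays called primary
#' interaction domains as bars under the track, the usual way 4C domain calls
#' are displayed.
#'
#' @param object a `vp_profile`.
#' @param layer which layer to draw.
#' @param domains optional `interaction_domain` rows to draw as bars.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.vp_profile <- function(object, layer = c("smoothed", "normalized", "raw"),
                                domains = NULL, ...) {
  layer <- match.arg(layer)
  vp <- attr(object, "viewpoint")
  df <- as_tibble(object)[!object$masked, ]
  df$y <- df[[layer]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint / 1e3, y = .data$y)) +
    ggplot2::geom_area(fill = "grey35") +
    ggplot2::geom_vline(xintercept = vp$position / 1e3,
                        linetype = "dashed", colour = "red3") +
    ggplot2::labs(
      x = sprintf("%s position (kb)", vp$chrom),
      y = sprintf("4C signal (%s)", layer),
      title = sprintf("%s (%s)", vp$name, vp$tissue)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(domains)) {
    dd <- dplyr::bind_rows(domains)
    ylo <- -0.04 * max(df$y, na.rm = TRUE)
    p <- p + ggplot2::annotate("segment",
      x = dd$start / 1e3, xend = dd$end / 1e3, y = ylo, yend = ylo,
      linewidth = 2, colour = "steelblue"
    )
  }
  p
}

#' Plot cumulative left/right signal curves
#'
#' @param object an `asymmetry_curve` from [cumulative_asymmetry()].
#' @param ... unused.
#' @return A ggplot of the two cumulative curves against distance.
#' @export
autoplot.asymmetry_curve <- function(object, ...) {
  vp <- attr(object, "viewpoint")
  long <- tidyr::pivot_longer(as_tibble(object),
    c("cumulative_left", "cumulative_right"),
    names_to = "side", values_to = "cumulative", names_prefix = "cumulative_"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$distance / 1e3, .data$cumulative,
                                     colour = .data$side)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance from viewpoint (kb)",
                  y = "cumulative normalized reads",
                  title = vp$name) +
    ggplot2::theme_minimal()
}

#' Plot a region-fraction summary
#'
#' @param object a `region_summary` from [region_fraction()].
#' @param ... unused.
#' @return A ggplot bar chart of signal percentages per region.
#' @export
autoplot.region_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$name <- factor(df$name, levels = df$name)
  ggplot2::ggplot(df, ggplot2::aes(.data$name, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "% of normalized reads") +
    ggplot2::theme_minimal()
}
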