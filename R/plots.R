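#' Raster plot of a network recording
#'
#' Spike raster (one row per unit) with detected bursts overlaid as segments
#' when a burst table is supplied.
#'
#' @param rec an [mea_recording()].
#' @param bursts optional burst table from [detect_bursts()].
#' @return A ggplot object.
#' @export
plot_raster <- function(rec, bursts = NULL) {
  stopifnot(inherits(rec, "mea_recording"))
  df <- mutate(rec$spikes,
               unit = factor(.data$unit_id, levels = rev(rec$units)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms / 1000,
                                        y = .data$unit)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("network %s", rec$network_id)) +
    ggplot2::theme_minimal()
  if (!is.null(bursts) && nrow(bursts) > 0L) {
    bd <- mutate(bursts, unit = factor(.data$unit_id, levels = rev(rec$units)))
    p <- p + ggplot2::geom_segment(
      data = bd,
      ggplot2::aes(x = .data$start_ms / 1000, xend = .data$end_ms / 1000,
                   y = .data$unit, yend = .data$unit),
      colour = "red", linewidth = 1.5, alpha = 0.5)
  }
  p
}

#' Plot percent-of-control group effects
#'
#' Bar chart of treatment means as percent of control for a comparison table,
#' annotated with significance stars.
#'
#' @param comparisons tibble from [compare_groups()] /
#'   [compare_feature_tables()].
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(comparisons) {
  stopifnot(is.data.frame(comparisons), "pct_of_control" %in% names(comparisons))
  df <- mutate(comparisons,
               parameter = factor(.data$parameter,
                                  levels = rev(unique(.data$parameter))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_of_control,
                                   y = .data$parameter)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 100, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.2) +
    ggplot2::labs(x = "treatment, % of control", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a cross-validation result
#'
#' Heatmap of the recognition percentages (true group x predicted group).
#'
#' @param object an `mea_cv` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mea_cv
#' @export
autoplot.mea_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$recognition_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", .data$recognition_pct)), colour = "white") +
    ggplot2::scale_fill_gradient(limits = c(0, 100), low = "grey30",
                                 high = "firebrick") +
    ggplot2::labs(x = "predicted group", y = "true group",
                  fill = "% recognized",
                  subtitle = sprintf("chi-squared p = %.3g", object$chi2_p)) +
    ggplot2::theme_minimal()
}

#' Plot the onset-aligned mean burst profile of a unit
#'
#' @param profiles result of [burst_profiles()].
#' @return A ggplot object.
#' @export
plot_burst_profile <- function(profiles) {
  df <- tibble(t = profiles$grid, rate = profiles$mean_profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.9 * max(df$rate), linetype = "dotted") +
    ggplot2::labs(x = "time from burst onset (ms)",
                  y = "instantaneous rate (Hz)") +
    ggplot2::theme_minimal()
}
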