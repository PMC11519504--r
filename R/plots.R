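#' Boxplots of per-cell 2H content by time point
#'
#' @param cells Cell tibble with `timepoint_h` and `f_at_percent` (and,
#'   optionally, an `active` column used for coloring).
#' @return A ggplot object.
#' @export
plot_cell_enrichment <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("timepoint_h", "f_at_percent") %in% names(cells)))
  p <- ggplot2::ggplot(
    cells,
    ggplot2::aes(factor(.data$timepoint_h), .data$f_at_percent)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.55)
  if ("active" %in% names(cells)) {
    p <- p + ggplot2::geom_jitter(
      ggplot2::aes(color = .data$active), width = 0.18, alpha = 0.5, size = 0.8
    )
  } else {
    p <- p + ggplot2::geom_jitter(width = 0.18, alpha = 0.4, size = 0.8)
  }
  p +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "hydration time (h)",
      y = expression({}^2 * H ~ "content (at%)"),
      color = "active"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of replication times by physiology scenario
#'
#' @param rates Output of [biomass_generation_rate()] (needs `tau_days` and
#'   `scenario`); saturated/infinite values are dropped from the display.
#' @param max_days Right edge of the display window (default 40).
#' @return A ggplot object.
#' @export
plot_replication_times <- function(rates, max_days = 40) {
  stopifnot(is.data.frame(rates),
            all(c("tau_days", "scenario") %in% names(rates)))
  shown <- dplyr::filter(rates, is.finite(.data$tau_days),
                         .data$tau_days <= max_days)
  ggplot2::ggplot(shown, ggplot2::aes(.data$tau_days, fill = .data$scenario)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "replication time (days)", y = "cells",
                  fill = "scenario") +
    ggplot2::theme_minimal()
}

#' Heatmap-style tile plot of per-MAG transcript shares
#'
#' @param shares Output of [mag_transcript_share()].
#' @return A ggplot object.
#' @export
plot_mag_share <- function(shares) {
  stopifnot(is.data.frame(shares),
            all(c("sample_id", "mag_id", "share") %in% names(shares)))
  ggplot2::ggplot(
    shares,
    ggplot2::aes(.data$sample_id, .data$mag_id, fill = .data$share)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "transcript\nshare") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
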