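#' Plot a wavelet energy surface
#'
#' Time-frequency heat map of `log10` energy with the cone of influence
#' drawn as a dashed line; the region below the line is unreliable.
#'
#' @param object A `cwt_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cwt_spectrum <- function(object, ...) {
  df <- tidy(object)
  coi <- tibble::tibble(time_s = object$times,
                        freq_hz = pmin(object$coi_hz, max(object$freqs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$energy + 1e-12))) +
    ggplot2::geom_line(data = coi, linetype = "dashed", colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "log10 E") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Box plots of per-episode band statistics
#'
#' One panel per statistic (`N`: patterns per second, `T`: occupancy), bands
#' on the x axis, one box per recording within each band — the per-animal
#' summary view of the normalized pattern statistics.
#'
#' @param summaries Tibble from [summarize_bands()].
#' @param statistic `"N"`, `"T"` or both.
#' @return A ggplot object.
#' @export
plot_band_summary <- function(summaries, statistic = c("N", "T")) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  long <- summaries |>
    tidyr::pivot_longer(cols = dplyr::all_of(statistic),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$band, y = .data$value,
                                     fill = .data$recording_id)) +
    ggplot2::geom_boxplot(outlier.shape = 4, position = "dodge") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 22,
                          position = ggplot2::position_dodge(width = 0.75)) +
    ggplot2::facet_grid(statistic ~ state, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "recording") +
    ggplot2::theme_minimal()
}

#' Plot delta comparisons against the minor-deviation band
#'
#' Per-subject delta values by band and state with the minor-deviation
#' interval shaded; the group view of the recording comparison.
#'
#' @param object A `delta_comparison` from [compare_recordings()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.delta_comparison <- function(object, ...) {
  minor_band <- attr(object, "minor_band") %||% c(0.95, 1.05)
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$band, y = .data$delta)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = minor_band[1], ymax = minor_band[2],
                      alpha = 0.2, fill = "grey40") +
    ggplot2::geom_boxplot(outlier.shape = 4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_grid(statistic ~ state) +
    ggplot2::labs(x = NULL, y = expression(delta)) +
    ggplot2::theme_minimal()
}
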