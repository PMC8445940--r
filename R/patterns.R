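#' The six fixed analysis bands
#'
#' Default bands: df1 \[1; 2.5\], df2 \[2.5; 4.5\], df3 \[4.5; 6.5\],
#' df4 \[6.5; 9\], df5 \[9; 12\], df6 \[12; 14\] Hz. Since the printed
#' intervals share their endpoints, binning is half-open `[low, high)` for
#' bands 1-5 with the final band closed at the top `[12, 14]`, which makes
#' band assignment total and deterministic.
#'
#' @param edges Ascending numeric vector of 7 band edges in Hz.
#' @return A `band_scheme` object.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(edges = c(1, 2.5, 4.5, 6.5, 9, 12, 14)) {
  edges <- as.numeric(edges)
  stopifnot(length(edges) >= 2, !is.unsorted(edges, strictly = TRUE))
  structure(list(edges = edges, n_bands = length(edges) - 1L),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  iv <- paste0("df", seq_len(x$n_bands), " [", x$edges[-length(x$edges)],
               "; ", x$edges[-1], ")")
  iv[x$n_bands] <- sub("\\)$", "]", iv[x$n_bands])
  cat("<band_scheme>", paste(iv, collapse = ", "), "Hz\n")
  invisible(x)
}

#' Band labels of a scheme
#' @param scheme A [band_scheme()].
#' @return Character vector `"df1"..."dfK"`.
#' @export
band_labels <- function(scheme = band_scheme()) {
  paste0("df", seq_len(scheme$n_bands))
}

#' Assign frequencies to analysis bands
#'
#' Half-open binning `[low, high)` for all bands except the last, which is
#' closed `[low, high]`; frequencies outside the scheme's range map to `NA`
#' (excluded from band statistics).
#'
#' @param f Numeric vector of (positive) frequencies in Hz.
#' @param scheme A [band_scheme()].
#' @return Integer vector of band indices (1-based) with `NA` for
#'   out-of-range frequencies.
#' @examples
#' bin_band(c(2.5, 14, 0.8))  # 2, 6, NA
#' @export
bin_band <- function(f, scheme = band_scheme()) {
  if (any(!is.na(f) & f <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  e <- scheme$edges
  idx <- findInterval(f, e, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1L | idx > scheme$n_bands] <- NA_integer_
  as.integer(idx)
}

#' Convert skeleton lines to oscillatory patterns
#'
#' Each skeleton line lasting at least the minimum duration becomes one
#' pattern with its unweighted mean frequency and band label. A line's
#' duration is its time support `end_s - start_s` where
#' `end_s = last point + dt` (half-open sample extents, matching the episode
#' convention), so an uninterrupted ridge across an episode of length L has
#' duration L.
#'
#' Two duration criteria are available. The default, `tau_mode = "cycles"`,
#' is frequency-fair: a candidate must last at least `min_cycles`
#' oscillation periods at its own mean frequency (`min_cycles / f_mean`
#' seconds), so slow bands are not penalized by a fixed threshold. The
#' alternative `tau_mode = "fixed"` uses `tau_min_s` seconds for every line.
#'
#' @param lines Tibble of skeleton points with `line_id` (see
#'   [skeleton_lines()]).
#' @param dt Time step of the spectrum in seconds (1 / sampling rate).
#' @param tau_mode `"cycles"` (default) or `"fixed"`.
#' @param min_cycles Minimum number of periods for `tau_mode = "cycles"`.
#' @param tau_min_s Minimum duration in seconds for `tau_mode = "fixed"`.
#' @param scheme A [band_scheme()].
#' @return A tibble with one row per pattern: `line_id`, `start_s`, `end_s`,
#'   `duration_s`, `n_points`, `f_mean`, `band` (integer, `NA` when `f_mean`
#'   is outside the scheme).
#' @export
to_patterns <- function(lines, dt, tau_mode = c("cycles", "fixed"),
                        min_cycles = 2, tau_min_s = 0.5,
                        scheme = band_scheme()) {
  tau_mode <- match.arg(tau_mode)
  stopifnot(is.data.frame(lines), dt > 0, min_cycles > 0, tau_min_s > 0)
  if (nrow(lines) == 0L) {
    return(empty_patterns())
  }
  pats <- lines |>
    dplyr::group_by(.data$line_id) |>
    dplyr::summarise(
      start_s = min(.data$time_s),
      end_s = max(.data$time_s) + dt,
      n_points = dplyr::n(),
      f_mean = mean(.data$freq_hz),
      .groups = "drop"
    ) |>
    dplyr::mutate(duration_s = .data$end_s - .data$start_s)
  tau <- if (tau_mode == "cycles") min_cycles / pats$f_mean else tau_min_s
  pats <- pats[pats$duration_s >= tau - 1e-12, , drop = FALSE]
  pats$band <- bin_band(pats$f_mean, scheme)
  dplyr::select(pats, "line_id", "start_s", "end_s", "duration_s",
                "n_points", "f_mean", "band")
}

empty_patterns <- function() {
  tibble::tibble(line_id = integer(), start_s = numeric(), end_s = numeric(),
                 duration_s = numeric(), n_points = integer(),
                 f_mean = numeric(), band = integer())
}
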