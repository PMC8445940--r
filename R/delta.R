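#' Symmetric ratio statistic comparing three recordings
#'
#' The comparison statistic `delta = 0.5 * (a1/a2 + a3/a2)`: the average of
#' the baseline and recovery aggregates, each taken relative to the
#' post-exposure aggregate. `delta = 1` when all three agree; values above 1
#' indicate a deficit in the post-exposure recording.
#'
#' @param a1,a2,a3 Aggregate values for the baseline, post-exposure and
#'   recovery recordings (vectors recycle). `a2` must be strictly positive —
#'   a zero denominator is an error here; [compare_recordings()] reports such
#'   cells as missing instead.
#' @return `0.5 * (a1/a2 + a3/a2)`.
#' @examples
#' delta_stat(0.2, 0.2, 0.2)  # 1
#' delta_stat(10, 8, 6)       # 1
#' @export
delta_stat <- function(a1, a2, a3) {
  if (any(a2 == 0, na.rm = TRUE)) {
    stop("undefined ratio: the post-exposure aggregate (a2) is zero",
         call. = FALSE)
  }
  0.5 * (a1 / a2 + a3 / a2)
}

delta_or_na <- function(a1, a2, a3) {
  ifelse(is.na(a2) | a2 == 0, NA_real_, 0.5 * (a1 + a3) / a2)
}

#' Compare baseline/exposed/recovery recordings per band
#'
#' Applies [delta_stat()] to the per-band aggregate `N` and `T` of three
#' recordings per subject and state, and classifies each value against the
#' band of minor deviations (default \[0.95; 1.05\]). Cells where the
#' post-exposure aggregate is zero are reported as missing (`NA` delta),
#' never as 0 or Inf.
#'
#' @param aggregates Tibble from [aggregate_bands()] containing all three
#'   recordings.
#' @param baseline,exposed,recovery Recording ids playing the ECoG1 / ECoG2 /
#'   ECoG3 roles.
#' @param minor_band Length-2 numeric: the minor-deviation interval.
#' @return A `delta_comparison` tibble: one row per subject x state x band
#'   with `delta_N`, `delta_T`, `minor_N`, `minor_T` (logical, `NA` when
#'   missing).
#' @export
compare_recordings <- function(aggregates, baseline = "ECoG1",
                               exposed = "ECoG2", recovery = "ECoG3",
                               minor_band = c(0.95, 1.05)) {
  stopifnot(is.data.frame(aggregates), length(minor_band) == 2)
  roles <- c(baseline, exposed, recovery)
  missing_rec <- setdiff(roles, unique(aggregates$recording_id))
  if (length(missing_rec) > 0L) {
    stop("aggregates lack recording(s): ", paste(missing_rec, collapse = ", "),
         call. = FALSE)
  }
  wide <- aggregates |>
    dplyr::filter(.data$recording_id %in% roles) |>
    dplyr::mutate(role = dplyr::case_when(
      .data$recording_id == baseline ~ "bl",
      .data$recording_id == exposed ~ "ex",
      TRUE ~ "rc"
    )) |>
    dplyr::select("subject_id", "state", "band", "role", "N_mean", "T_mean") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("N_mean", "T_mean"))
  need <- c("N_mean_bl", "N_mean_ex", "N_mean_rc",
            "T_mean_bl", "T_mean_ex", "T_mean_rc")
  if (!all(need %in% names(wide)) || anyNA(wide[need])) {
    stop("inconsistent aggregates: every subject x state x band must be ",
         "present for all three recordings", call. = FALSE)
  }
  out <- wide |>
    dplyr::mutate(
      delta_N = delta_or_na(.data$N_mean_bl, .data$N_mean_ex, .data$N_mean_rc),
      delta_T = delta_or_na(.data$T_mean_bl, .data$T_mean_ex, .data$T_mean_rc),
      minor_N = .data$delta_N >= minor_band[1] & .data$delta_N <= minor_band[2],
      minor_T = .data$delta_T >= minor_band[1] & .data$delta_T <= minor_band[2]
    ) |>
    dplyr::select("subject_id", "state", "band", "delta_N", "delta_T",
                  "minor_N", "minor_T") |>
    dplyr::arrange(.data$subject_id, .data$state, .data$band)
  attr(out, "minor_band") <- minor_band
  class(out) <- c("delta_comparison", class(out))
  out
}

#' Group-level summary of delta comparisons
#'
#' Per-subject delta values are computed first ([compare_recordings()]), then
#' summarized across subjects by median and interquartile range — no
#' cross-subject pooling happens before the ratio.
#'
#' @param deltas A `delta_comparison` tibble (possibly many subjects).
#' @param by Grouping columns (default state and band).
#' @return A tibble with `delta_N_median`, `delta_N_iqr`, `delta_T_median`,
#'   `delta_T_iqr`, `n_subjects`, and `minor_N` / `minor_T` flags for the
#'   medians.
#' @export
summarize_deltas <- function(deltas, by = c("state", "band")) {
  stopifnot(is.data.frame(deltas))
  minor_band <- attr(deltas, "minor_band") %||% c(0.95, 1.05)
  deltas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      delta_N_median = stats::median(.data$delta_N, na.rm = TRUE),
      delta_N_iqr = stats::IQR(.data$delta_N, na.rm = TRUE),
      delta_T_median = stats::median(.data$delta_T, na.rm = TRUE),
      delta_T_iqr = stats::IQR(.data$delta_T, na.rm = TRUE),
      n_subjects = dplyr::n_distinct(.data$subject_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      minor_N = .data$delta_N_median >= minor_band[1] &
        .data$delta_N_median <= minor_band[2],
      minor_T = .data$delta_T_median >= minor_band[1] &
        .data$delta_T_median <= minor_band[2]
    )
}

#' @export
glance.delta_comparison <- function(x, ...) {
  tibble::tibble(
    n_subjects = dplyr::n_distinct(x$subject_id),
    n_cells = sum(!is.na(x$delta_N)) + sum(!is.na(x$delta_T)),
    n_minor = sum(x$minor_N, na.rm = TRUE) + sum(x$minor_T, na.rm = TRUE),
    n_missing = sum(is.na(x$delta_N)) + sum(is.na(x$delta_T))
  )
}

#' @export
tidy.delta_comparison <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = c("delta_N", "delta_T"),
    names_to = "statistic", names_prefix = "delta_",
    values_to = "delta"
  ) |>
    dplyr::mutate(minor = ifelse(.data$statistic == "N",
                                 .data$minor_N, .data$minor_T)) |>
    dplyr::select("subject_id", "state", "band", "statistic", "delta", "minor")
}
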