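#' Per-episode normalized band statistics
#'
#' For each episode and band, computes the normalized pattern number
#' `N = count / L` (patterns per second) and normalized duration
#' `T = sum(duration) / L` (dimensionless occupancy), where `L` is the
#' episode length in seconds. Normalizing by episode length makes episodes of
#' unequal duration comparable, which the sleep/wake design requires.
#' Patterns whose mean frequency falls outside the band scheme (`band = NA`)
#' are excluded.
#'
#' @param patterns Pattern tibble from [detect_patterns()] /
#'   [detect_episodes()] (must carry `episode_duration_s`).
#' @param scheme A [band_scheme()]; defines the set of bands reported (zero
#'   rows are filled in for empty bands).
#' @param episodes Optional episode table (e.g. from [split_episodes()])
#'   giving the full set of analyzed episodes; episodes without any detected
#'   pattern then still contribute all-zero rows. When `NULL`, the episode
#'   set is inferred from the patterns themselves.
#' @return A tibble with one row per episode x band: `subject_id`,
#'   `recording_id`, `episode_id`, `state`, `episode_duration_s`, `band`
#'   (factor `df1...dfK`), `n_patterns`, `N` (1/s), `T` (dimensionless).
#' @examples
#' # 60 s episode with 6 df1 patterns totalling 12 s: N = 0.1 /s, T = 0.2
#' @export
summarize_bands <- function(patterns, scheme = band_scheme(),
                            episodes = NULL) {
  stopifnot(is.data.frame(patterns))
  labs <- band_labels(scheme)
  if (nrow(patterns) > 0 && any(patterns$episode_duration_s <= 0, na.rm = TRUE)) {
    stop("degenerate episode: episode_duration_s must be > 0", call. = FALSE)
  }
  keys <- c("subject_id", "recording_id", "episode_id", "state",
            "episode_duration_s")
  if (is.null(episodes)) {
    episodes <- dplyr::distinct(patterns, dplyr::across(dplyr::all_of(keys)))
  } else {
    episodes <- episodes |>
      dplyr::rename(dplyr::any_of(c(episode_duration_s = "duration_s"))) |>
      dplyr::distinct(dplyr::across(dplyr::all_of(keys)))
    if (any(episodes$episode_duration_s <= 0)) {
      stop("degenerate episode: episode_duration_s must be > 0",
           call. = FALSE)
    }
  }
  if (nrow(episodes) == 0L) {
    return(tibble::tibble(
      subject_id = character(), recording_id = character(),
      episode_id = integer(), state = character(),
      episode_duration_s = numeric(),
      band = factor(character(), levels = labs),
      n_patterns = integer(), N = numeric(), T = numeric()
    ))
  }
  grid <- tidyr::crossing(episodes, band = factor(labs, levels = labs))
  counted <- patterns |>
    dplyr::filter(!is.na(.data$band)) |>
    dplyr::mutate(band = factor(labs[.data$band], levels = labs)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "band")))) |>
    dplyr::summarise(n_patterns = dplyr::n(),
                     total_dur = sum(.data$duration_s), .groups = "drop")
  grid |>
    dplyr::left_join(counted, by = c(keys, "band")) |>
    dplyr::mutate(
      n_patterns = dplyr::coalesce(.data$n_patterns, 0L),
      total_dur = dplyr::coalesce(.data$total_dur, 0),
      N = .data$n_patterns / .data$episode_duration_s,
      T = .data$total_dur / .data$episode_duration_s
    ) |>
    dplyr::select(-"total_dur") |>
    dplyr::arrange(.data$subject_id, .data$recording_id, .data$episode_id,
                   .data$band)
}

#' Aggregate episode band statistics to recording level
#'
#' Unweighted arithmetic mean of the per-episode `N` and `T` over all
#' episodes of one state within one recording (each episode contributes
#' equally regardless of its length); `weighted = TRUE` instead weights
#' episodes by duration.
#'
#' @param summaries Tibble from [summarize_bands()].
#' @param weighted Duration-weight the episode mean? Default `FALSE`.
#' @return A tibble with one row per subject x recording x state x band:
#'   `N_mean`, `T_mean`, `n_episodes`.
#' @export
aggregate_bands <- function(summaries, weighted = FALSE) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0L) {
    stop("no episode summaries to aggregate", call. = FALSE)
  }
  summaries |>
    dplyr::group_by(.data$subject_id, .data$recording_id, .data$state,
                    .data$band) |>
    dplyr::summarise(
      N_mean = if (weighted) {
        stats::weighted.mean(.data$N, .data$episode_duration_s)
      } else mean(.data$N),
      T_mean = if (weighted) {
        stats::weighted.mean(.data$T, .data$episode_duration_s)
      } else mean(.data$T),
      n_episodes = dplyr::n_distinct(.data$episode_id),
      .groups = "drop"
    )
}
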