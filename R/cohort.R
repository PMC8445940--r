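#' Generate a synthetic three-recording cohort with ground truth
#'
#' Emulates the experimental design the package analyzes: for each subject,
#' three recordings (baseline `ECoG1`, post-exposure `ECoG2`, recovery
#' `ECoG3`), each consisting of alternating awake/sleep episodes. Bursts are
#' drawn per band and episode as a Poisson process at `burst_rate_per_min`;
#' in the exposed recording the rates are multiplied by the state-specific
#' `exposed_multiplier` (defaults mirror a mild suppression of oscillatory
#' events after exposure: 0.87 awake, 0.92 sleep). The whole cohort is a
#' pure function of its arguments including `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param fs Sampling rate in Hz.
#' @param episode_s Length of each episode in seconds.
#' @param n_episodes Episodes per state per recording (total duration per
#'   state is `n_episodes * episode_s`).
#' @param burst_rate_per_min Bursts per minute per band (scalar or one value
#'   per band).
#' @param exposed_multiplier Named numeric `c(awake = ..., sleep = ...)`
#'   multiplying the exposed recording's rates.
#' @param amplitude Burst SNR relative to unit-RMS background.
#' @param beta Background spectral exponent.
#' @param cycles_range Burst lengths are drawn uniformly in this range of
#'   oscillation cycles at the burst's own frequency.
#' @param scheme [band_scheme()] the burst frequencies are drawn from.
#' @param seed Integer seed fixing the full cohort.
#' @return A tibble with one row per subject x recording: `subject_id`,
#'   `recording_id`, and list-columns `series` ([ecog_ts()]), `annotations`
#'   (tibble `start_s,end_s,state`), `truth` (burst table with `state`).
#' @export
gen_cohort <- function(n_subjects = 10, fs = 100, episode_s = 100,
                       n_episodes = 3, burst_rate_per_min = 10,
                       exposed_multiplier = c(awake = 0.87, sleep = 0.92),
                       amplitude = 5, beta = 1, cycles_range = c(4, 8),
                       scheme = band_scheme(), seed = 1) {
  stopifnot(n_subjects >= 0, episode_s > 0, n_episodes >= 1,
            all(burst_rate_per_min >= 0),
            all(c("awake", "sleep") %in% names(exposed_multiplier)))
  rates <- rep_len(burst_rate_per_min, scheme$n_bands)
  if (n_subjects == 0L) {
    return(tibble::tibble(subject_id = character(),
                          recording_id = character(),
                          series = list(), annotations = list(),
                          truth = list()))
  }
  states <- rep(c("awake", "sleep"), times = n_episodes)
  n_ep_total <- length(states)
  ann <- tibble::tibble(
    start_s = (seq_len(n_ep_total) - 1) * episode_s,
    end_s = seq_len(n_ep_total) * episode_s,
    state = states
  )
  with_seed(seed, {
    rows <- list()
    for (subj in seq_len(n_subjects)) {
      for (rec in c("ECoG1", "ECoG2", "ECoG3")) {
        ep_signals <- vector("list", n_ep_total)
        truth_all <- list()
        for (k in seq_len(n_ep_total)) {
          mult <- if (rec == "ECoG2") {
            unname(exposed_multiplier[[states[k]]])
          } else 1
          bursts <- draw_episode_bursts(episode_s, rates * mult, amplitude,
                                        cycles_range, scheme)
          sig <- gen_signal(fs, episode_s, bursts, beta = beta, seed = NULL)
          ep_signals[[k]] <- sig$ts$samples
          if (nrow(sig$truth) > 0L) {
            tr <- sig$truth
            tr$t_start <- tr$t_start + ann$start_s[k]
            tr$state <- states[k]
            truth_all[[length(truth_all) + 1L]] <- tr
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sprintf("subject%02d", subj),
          recording_id = rec,
          series = list(ecog_ts(unlist(ep_signals), fs = fs,
                                channel = "sim")),
          annotations = list(ann),
          truth = list(if (length(truth_all)) {
            dplyr::bind_rows(truth_all)
          } else cbind_state_empty())
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

cbind_state_empty <- function() {
  out <- empty_truth()
  out$state <- character()
  out
}

# Poisson burst draw for one episode: per band, counts at the given rate,
# onsets uniform so each burst lies fully inside the episode. Frequencies
# are drawn from the interior of the band (15% margin per side) so that the
# ground-truth band label of every burst is unambiguous under detection
# noise.
draw_episode_bursts <- function(episode_s, rates_per_min, amplitude,
                                cycles_range, scheme) {
  out <- list()
  for (b in seq_len(scheme$n_bands)) {
    lambda <- rates_per_min[b] * episode_s / 60
    count <- stats::rpois(1, lambda)
    if (count == 0L) next
    w <- scheme$edges[b + 1] - scheme$edges[b]
    f0 <- stats::runif(count, scheme$edges[b] + 0.15 * w,
                       scheme$edges[b + 1] - 0.15 * w)
    cycles <- stats::runif(count, cycles_range[1], cycles_range[2])
    dur <- pmax(cycles, 2.001) / f0
    dur <- pmin(dur, episode_s / 2)
    t0 <- stats::runif(count, 0, episode_s - dur)
    out[[length(out) + 1L]] <- burst_spec(t0, dur, f0, amplitude)
  }
  if (length(out) == 0L) {
    return(NULL)
  }
  dplyr::bind_rows(out)
}

#' Write a synthetic cohort to a file tree
#'
#' One directory per subject containing, per recording, a two-column signal
#' CSV (`time_s,value`), an annotation CSV (`start_s,end_s,state`), and a
#' combined `ground_truth.csv` across recordings.
#'
#' @param cohort Tibble from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in unique(cohort$subject_id)) {
    sd <- file.path(dir, subj)
    dir.create(sd, showWarnings = FALSE)
    sub <- cohort[cohort$subject_id == subj, ]
    truths <- list()
    for (i in seq_len(nrow(sub))) {
      rec <- sub$recording_id[i]
      write_timeseries_csv(sub$series[[i]], file.path(sd, paste0(rec, ".csv")))
      utils::write.csv(sub$annotations[[i]],
                       file.path(sd, paste0(rec, "_annotations.csv")),
                       row.names = FALSE, quote = FALSE)
      tr <- sub$truth[[i]]
      if (nrow(tr) > 0L) {
        tr$subject_id <- subj
        tr$recording_id <- rec
        truths[[length(truths) + 1L]] <- tr
      }
    }
    gt <- if (length(truths)) dplyr::bind_rows(truths) else cbind_state_empty()
    utils::write.csv(gt, file.path(sd, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Run the detection pipeline over a cohort
#'
#' Splits every recording into its annotated episodes, detects patterns per
#' episode, computes band summaries and recording-level aggregates, and the
#' per-subject delta comparison of the three recordings.
#'
#' @param cohort Tibble from [gen_cohort()] (or of the same shape with real
#'   data).
#' @param settings A [detect_settings()].
#' @param states Which states to analyze (default both); restricting saves
#'   time when only one state is of interest.
#' @return A list with `patterns`, `summaries`, `aggregates` (tibbles) and
#'   `deltas` (a `delta_comparison`), plus `group` (the [summarize_deltas()]
#'   table).
#' @export
analyze_cohort <- function(cohort, settings = detect_settings(),
                           states = c("awake", "sleep")) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  all_eps <- list()
  pats <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    eps <- split_episodes(cohort$series[[i]], cohort$annotations[[i]],
                          recording_id = cohort$recording_id[i],
                          subject_id = cohort$subject_id[i])
    eps <- eps[eps$state %in% states, , drop = FALSE]
    all_eps[[i]] <<- eps[setdiff(names(eps), "series")]
    detect_episodes(eps, settings)
  })
  summaries <- summarize_bands(pats, settings$scheme,
                               episodes = dplyr::bind_rows(all_eps))
  aggregates <- aggregate_bands(summaries)
  deltas <- compare_recordings(aggregates)
  list(patterns = pats, summaries = summaries, aggregates = aggregates,
       deltas = deltas, group = summarize_deltas(deltas))
}
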