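#' Construct an ECoG/EEG time series
#'
#' A light container for a regularly sampled single-channel signal. Amplitude
#' units are arbitrary (typically microvolts); all downstream pattern
#' detection is amplitude-scale invariant, so no unit bookkeeping is done.
#'
#' @param samples Numeric vector of samples (non-empty, finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel Channel label.
#' @param t0 Start time of the first sample in seconds.
#'
#' @return An object of class `ecog_ts` with fields `samples`, `fs`,
#'   `channel`, `t0`.
#' @examples
#' ts <- ecog_ts(sin(2 * pi * 5 * seq(0, 10, by = 0.01)), fs = 100)
#' ts_duration(ts)
#' @export
ecog_ts <- function(samples, fs, channel = "ch1", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel = as.character(channel), t0 = as.numeric(t0)),
    class = "ecog_ts"
  )
}

#' @export
print.ecog_ts <- function(x, ...) {
  cat(sprintf("<ecog_ts> channel '%s': %d samples @ %g Hz, %.3f s (t0 = %g s)\n",
              x$channel, length(x$samples), x$fs, ts_duration(x), x$t0))
  invisible(x)
}

#' Duration of a time series in seconds
#'
#' @param ts An [ecog_ts()] object.
#' @return Duration `length(samples) / fs` in seconds.
#' @export
ts_duration <- function(ts) {
  stopifnot(inherits(ts, "ecog_ts"))
  length(ts$samples) / ts$fs
}

#' Sample time stamps of a time series
#'
#' @param ts An [ecog_ts()] object.
#' @return Numeric vector `t0 + (0:(n-1)) / fs`.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "ecog_ts"))
  ts$t0 + (seq_along(ts$samples) - 1) / ts$fs
}

#' Read a time series from CSV or EDF
#'
#' CSV files must either have columns `time_s,value` (uniformly spaced time
#' stamps, tolerance 1e-6 s) or a single `value` column together with
#' `fs_override`. EDF (European Data Format, 16-bit continuous) files are read
#' with physical-unit scaling applied; `channel` selects the signal by label.
#'
#' @param path Path to a `.csv` or `.edf` file.
#' @param channel Channel label (required for multi-channel EDF; used as the
#'   label for CSV input).
#' @param fs_override Sampling rate in Hz, required for one-column CSV,
#'   optional override otherwise.
#'
#' @return An [ecog_ts()].
#' @export
read_timeseries <- function(path, channel = NULL, fs_override = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    return(read_edf_channel(path, channel = channel, fs_override = fs_override))
  }
  if (!ext %in% c("csv", "txt", "tsv", "")) {
    stop("unknown signal format: '.", ext, "' (expected .csv or .edf)",
         call. = FALSE)
  }
  df <- utils::read.csv(path)
  label <- if (is.null(channel)) "ch1" else channel
  if (all(c("time_s", "value") %in% names(df))) {
    tt <- df$time_s
    if (length(tt) < 2L) {
      stop("two-column CSV needs at least 2 samples", call. = FALSE)
    }
    dt <- diff(tt)
    if (max(dt) - min(dt) > 1e-6 || any(dt <= 0)) {
      stop("non-uniform time column in ", path,
           " (spacing varies by more than 1e-6 s)", call. = FALSE)
    }
    fs <- if (!is.null(fs_override)) fs_override else 1 / mean(dt)
    return(ecog_ts(df$value, fs = fs, channel = label, t0 = tt[1]))
  }
  if ("value" %in% names(df) && ncol(df) == 1L) {
    if (is.null(fs_override)) {
      stop("one-column CSV requires `fs_override`", call. = FALSE)
    }
    return(ecog_ts(df$value, fs = fs_override, channel = label))
  }
  stop("CSV must have columns `time_s,value` or a single `value` column",
       call. = FALSE)
}

#' Write a time series to CSV
#'
#' Writes either a two-column `time_s,value` file (default) or a one-column
#' `value` file. Round-trips through [read_timeseries()] bit-exactly for the
#' samples and to ~1e-9 relative for `fs`.
#'
#' @param ts An [ecog_ts()].
#' @param path Output path.
#' @param time_column Include the `time_s` column?
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path, time_column = TRUE) {
  stopifnot(inherits(ts, "ecog_ts"))
  if (time_column) {
    df <- data.frame(time_s = ts_times(ts), value = ts$samples)
  } else {
    df <- data.frame(value = ts$samples)
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sleep/wake state annotation table
#'
#' @param path CSV with header `start_s,end_s,state`.
#' @return A tibble with those columns, validated by [validate_annotations()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns start_s,end_s,state", call. = FALSE)
  }
  validate_annotations(tibble::as_tibble(df[need]))
}

#' Validate a state annotation table
#'
#' Checks that every interval has `start_s < end_s`, that intervals do not
#' overlap, and that states are drawn from `{awake, sleep}`. Intervals are
#' half-open `[start_s, end_s)`, so a shared boundary is not an overlap.
#'
#' @param ann Data frame with columns `start_s`, `end_s`, `state`.
#' @return The annotations as a tibble ordered by `start_s`.
#' @export
validate_annotations <- function(ann) {
  ann <- tibble::as_tibble(ann)
  stopifnot(all(c("start_s", "end_s", "state") %in% names(ann)))
  if (nrow(ann) == 0L) {
    return(ann)
  }
  if (!all(ann$state %in% c("awake", "sleep"))) {
    bad <- setdiff(unique(ann$state), c("awake", "sleep"))
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         " (allowed: awake, sleep)", call. = FALSE)
  }
  if (any(ann$start_s >= ann$end_s)) {
    stop("every annotation interval must have start_s < end_s", call. = FALSE)
  }
  ann <- dplyr::arrange(ann, .data$start_s)
  if (nrow(ann) > 1L &&
      any(ann$start_s[-1] < ann$end_s[-nrow(ann)] - 1e-12)) {
    stop("annotation intervals overlap", call. = FALSE)
  }
  ann
}

#' Split a recording into state-labeled episodes
#'
#' Cuts the signal at the annotated intervals. Intervals are half-open
#' `[start_s, end_s)`; the sample index range is `floor(start * fs)` to
#' `floor(end * fs) - 1` relative to `t0`, so a shared boundary sample is
#' never counted twice. Stretches without annotation are dropped.
#'
#' @param ts An [ecog_ts()].
#' @param ann Annotation table (see [validate_annotations()]).
#' @param recording_id Recording label, e.g. `"ECoG1"`.
#' @param subject_id Subject label.
#' @return A tibble with one row per episode: `subject_id`, `recording_id`,
#'   `episode_id`, `state`, `start_s`, `end_s`, `duration_s` and a list-column
#'   `series` of [ecog_ts()] slices, in chronological order.
#' @export
split_episodes <- function(ts, ann, recording_id = "ECoG1",
                           subject_id = "subject1") {
  stopifnot(inherits(ts, "ecog_ts"))
  ann <- validate_annotations(ann)
  dur <- ts_duration(ts)
  if (nrow(ann) == 0L) {
    return(tibble::tibble(
      subject_id = character(), recording_id = character(),
      episode_id = integer(), state = character(),
      start_s = numeric(), end_s = numeric(), duration_s = numeric(),
      series = list()
    ))
  }
  lo <- ts$t0
  hi <- ts$t0 + dur
  if (any(ann$start_s < lo - 1e-9) || any(ann$end_s > hi + 1e-9)) {
    stop("annotation interval outside the recording [",
         format(lo), ", ", format(hi), "] s", call. = FALSE)
  }
  n <- length(ts$samples)
  purrr::pmap_dfr(
    list(ann$start_s, ann$end_s, ann$state, seq_len(nrow(ann))),
    function(s0, s1, state, k) {
      # epsilon guards against cut times that are exact sample instants
      # landing one sample low through floating-point rounding
      i0 <- floor((s0 - ts$t0) * ts$fs + 1e-9) + 1
      i1 <- min(floor((s1 - ts$t0) * ts$fs + 1e-9), n)
      if (i1 < i0) {
        stop("annotation interval [", s0, ", ", s1,
             ") contains no samples", call. = FALSE)
      }
      slice <- ecog_ts(ts$samples[i0:i1], fs = ts$fs, channel = ts$channel,
                       t0 = ts$t0 + (i0 - 1) / ts$fs)
      tibble::tibble(
        subject_id = subject_id, recording_id = recording_id,
        episode_id = k, state = state,
        start_s = s0, end_s = s1, duration_s = ts_duration(slice),
        series = list(slice)
      )
    }
  )
}
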