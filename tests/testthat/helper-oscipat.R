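# shared fixtures, all generated in code

make_tone <- function(f0, dur = 30, fs = 100, amp = 1, phase = 0) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  ecog_ts(amp * sin(2 * pi * f0 * tt + phase), fs = fs,
          channel = sprintf("tone%g", f0))
}

band_centers <- c(1.75, 3.5, 5.5, 7.75, 10.5, 13)

# independent CWT oracle: direct time-domain convolution with the
# closed-form analytic Morlet kernel (flat normalization), no FFT
direct_cwt <- function(ts, f, t_index, omega0 = 2 * pi) {
  x <- ts$samples - mean(ts$samples)
  dt <- 1 / ts$fs
  s <- omega0 / (2 * pi * f)
  tau <- (seq_along(x) - t_index) * dt
  h <- (dt / (s * sqrt(2 * pi))) * exp(-tau^2 / (2 * s^2)) *
    exp(1i * omega0 * tau / s)
  sum(x * h)
}

# construct a skeleton-line tibble directly (bypassing the CWT) for unit
# tests of to_patterns(); times start at t0, step dt
make_line <- function(freqs, dt = 0.01, t0 = 0, line_id = 1L, energy = 1) {
  n <- length(freqs)
  tibble::tibble(
    line_id = line_id,
    t_idx = seq_len(n),
    time_s = t0 + (seq_len(n) - 1) * dt,
    f_idx = seq_len(n),
    freq_hz = freqs,
    energy = rep_len(energy, n)
  )
}

# patterns table row(s) shaped like detect_episodes() output
make_patterns <- function(episode_id, state, L, band, duration_s,
                          subject_id = "s1", recording_id = "ECoG1") {
  n <- max(length(band), length(duration_s))
  tibble::tibble(
    subject_id = subject_id, recording_id = recording_id,
    episode_id = episode_id, state = state, episode_duration_s = L,
    start_s = 0, end_s = rep_len(duration_s, n),
    duration_s = rep_len(duration_s, n), n_points = 10L,
    f_mean = band_centers[rep_len(band, n)], band = rep_len(band, n)
  )
}

# ground-truth resolvable events per band: bursts whose half-maximum
# (FWHM) envelope supports overlap count as one event
resolvable_events <- function(bursts, n_bands = 6) {
  bursts <- flag_band_overlaps_local(bursts)
  vapply(seq_len(n_bands), function(b) {
    bb <- bursts[!is.na(bursts$band) & bursts$band == b, ]
    if (nrow(bb) == 0L) return(0L)
    lo <- bb$t_start + bb$duration / 4
    hi <- bb$t_start + 3 * bb$duration / 4
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    n <- 1L
    end <- hi[1]
    for (i in seq_along(lo)[-1]) {
      if (lo[i] > end) {
        n <- n + 1L
        end <- hi[i]
      } else {
        end <- max(end, hi[i])
      }
    }
    n
  }, 1L)
}

flag_band_overlaps_local <- function(bursts) {
  bursts$band <- bin_band(bursts$f0)
  bursts
}

# non-overlapping bursts at band-center frequencies for recovery tests
spaced_bursts <- function(K, centers, spacing = 11, min_dur = 1.2) {
  f0 <- centers[seq_len(K)]
  dur <- pmax(3 / f0, min_dur)
  burst_spec((seq_len(K) - 1) * spacing + 3, dur, f0, amplitude = 5)
}
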