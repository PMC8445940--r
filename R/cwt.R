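#' Wavelet analysis parameters
#'
#' Parameters of the complex Morlet continuous wavelet transform used for
#' pattern detection. The default central parameter `omega0 = 2*pi` gives the
#' convenient scale-frequency map `f = 1/s`; the default grid is linear from
#' 0.5 to 16 Hz in 0.05 Hz steps (311 points), covering the six analysis
#' bands (1-14 Hz) with margin so band-edge ridges stay resolvable.
#'
#' @param omega0 Dimensionless Morlet central frequency parameter (>= 5 for
#'   the analytic approximation to be admissible).
#' @param f_min,f_max Frequency grid limits in Hz.
#' @param n_freq Number of (linearly spaced) grid frequencies.
#' @param coi_factor Width of the flagged edge region, in units of the
#'   e-folding time `sqrt(2)*s` per scale. The default 2 is deliberately
#'   conservative: at one e-folding time an edge transient is only down to
#'   `1/e` in amplitude and its ridge (which runs parallel to the cone
#'   boundary) can still exceed a permissive noise floor; at two e-folding
#'   times it is down by ~e^-8 in energy.
#' @return A `wavelet_params` list.
#' @examples
#' wavelet_params()
#' @export
wavelet_params <- function(omega0 = 2 * pi, f_min = 0.5, f_max = 16,
                           n_freq = 311, coi_factor = 2) {
  stopifnot(f_min > 0, f_max > f_min, n_freq >= 2, omega0 >= 5,
            coi_factor > 0)
  structure(list(omega0 = omega0, f_min = f_min, f_max = f_max,
                 n_freq = as.integer(n_freq), coi_factor = coi_factor),
            class = "wavelet_params")
}

#' @export
print.wavelet_params <- function(x, ...) {
  cat(sprintf(
    "<wavelet_params> Morlet omega0 = %.4g; grid %g-%g Hz, %d points (step %.4g Hz)\n",
    x$omega0, x$f_min, x$f_max, x$n_freq,
    (x$f_max - x$f_min) / (x$n_freq - 1)))
  invisible(x)
}

params_freqs <- function(params) {
  seq(params$f_min, params$f_max, length.out = params$n_freq)
}

#' Continuous wavelet transform energy surface
#'
#' Computes `E(f, t) = |W(s(f), t)|^2` with the analytic complex Morlet
#' wavelet, via one FFT-based convolution per scale, on the frequency grid of
#' `params`. The scale-frequency map is `f = omega0 / (2*pi*s)`. Per-scale
#' amplitude (flat) normalization is used, so the response to a pure tone
#' peaks exactly at the tone frequency. The signal mean is removed before
#' transforming.
#'
#' Edge effects are tracked with a cone of influence (COI) of
#' `coi_factor` e-folding times: at time distance `d` from the nearer edge,
#' frequencies below `coi_factor * sqrt(2) * omega0 / (2*pi*d)` are flagged
#' unreliable. Columns are never deleted; `coi_hz` records the per-column
#' minimum trustworthy frequency.
#'
#' @param ts An [ecog_ts()]; its duration must be at least `2 / f_min` (two
#'   periods of the slowest analyzed frequency).
#' @param params A [wavelet_params()].
#' @return A `cwt_spectrum` object with fields `energy` (`n_freq` x `n_time`
#'   matrix), `freqs` (Hz, ascending), `times` (s), `coi_hz` (per-time minimum
#'   reliable frequency, Hz), `fs`, and `params`.
#' @examples
#' ts <- ecog_ts(sin(2 * pi * 5 * seq(0, 30, by = 0.01)), fs = 100)
#' spec <- compute_cwt(ts)
#' spec$freqs[which.max(spec$energy[, ncol(spec$energy) %/% 2])]
#' @export
compute_cwt <- function(ts, params = wavelet_params()) {
  stopifnot(inherits(ts, "ecog_ts"), inherits(params, "wavelet_params"))
  dur <- ts_duration(ts)
  if (dur < 2 / params$f_min) {
    stop(sprintf(
      "signal too short: %.3f s < 2/f_min = %.3f s (need two periods of the slowest frequency)",
      dur, 2 / params$f_min), call. = FALSE)
  }
  x <- ts$samples - mean(ts$samples)
  n <- length(x)
  dt <- 1 / ts$fs
  n2 <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, numeric(n2 - n)))
  # angular frequencies of the FFT bins
  k <- 0:(n2 - 1)
  omega <- ifelse(k <= n2 / 2, k, k - n2) * (2 * pi / (n2 * dt))
  freqs <- params_freqs(params)
  scales <- params$omega0 / (2 * pi * freqs)
  energy <- matrix(0, nrow = length(freqs), ncol = n)
  pos <- omega > 0
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi_hat <- numeric(n2)
    # analytic Morlet, flat (amplitude) normalization per scale
    psi_hat[pos] <- exp(-0.5 * (s * omega[pos] - params$omega0)^2)
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / n2
    energy[i, ] <- Mod(w[seq_len(n)])^2
  }
  times <- ts_times(ts)
  d <- pmin(times - times[1], times[n] - times) + dt / 2
  coi_hz <- params$coi_factor * sqrt(2) * params$omega0 / (2 * pi * d)
  structure(
    list(energy = energy, freqs = freqs, times = times, coi_hz = coi_hz,
         fs = ts$fs, params = params),
    class = "cwt_spectrum"
  )
}

#' @export
print.cwt_spectrum <- function(x, ...) {
  cat(sprintf(
    "<cwt_spectrum> %d freqs (%g-%g Hz) x %d times (%.3f-%.3f s)\n",
    length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# logical matrix: TRUE where (f, t) lies inside the cone of influence
coi_interior <- function(spec) {
  outer(spec$freqs, spec$coi_hz, `>=`)
}

#' Export a wavelet spectrum as a long tibble
#'
#' @param x A `cwt_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `freq_hz`, `energy`, `in_coi`
#'   (TRUE where the point is inside the reliable region).
#' @export
tidy.cwt_spectrum <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$times, each = length(x$freqs)),
    freq_hz = rep(x$freqs, times = length(x$times)),
    energy = as.vector(x$energy),
    in_coi = as.vector(coi_interior(x))
  )
}
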