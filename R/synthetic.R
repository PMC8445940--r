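# run code under a temporary RNG state when a seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a transient oscillatory burst
#'
#' A burst is an enveloped sinusoid added to the synthetic background. The
#' raised-cosine (Hann) envelope spans `[t_start, t_start + duration]`; its
#' full width at half maximum — the unambiguous ground-truth duration — is
#' `duration / 2`. Arguments recycle, so vectors build several bursts at
#' once.
#'
#' @param t_start Burst onset in seconds.
#' @param duration Envelope support in seconds; must be at least two periods
#'   (`2 / f0`).
#' @param f0 Burst frequency in Hz, within \[0.5, 16\].
#' @param amplitude Peak amplitude relative to the unit-RMS background (the
#'   burst SNR).
#' @return A tibble with columns `t_start`, `duration`, `f0`, `amplitude`.
#' @examples
#' burst_spec(10, 2, 5.5, amplitude = 5)
#' @export
burst_spec <- function(t_start, duration, f0, amplitude = 5) {
  df <- tibble::tibble(t_start = as.numeric(t_start),
                       duration = as.numeric(duration),
                       f0 = as.numeric(f0),
                       amplitude = as.numeric(amplitude))
  if (any(df$f0 < 0.5 | df$f0 > 16)) {
    stop("burst frequency f0 must lie in [0.5, 16] Hz", call. = FALSE)
  }
  if (any(df$duration < 2 / df$f0)) {
    stop("burst duration must be at least two periods (2 / f0)",
         call. = FALSE)
  }
  if (any(df$t_start < 0) || any(df$amplitude <= 0)) {
    stop("t_start must be >= 0 and amplitude > 0", call. = FALSE)
  }
  df
}

# 1/f^beta Gaussian background of unit RMS via spectral shaping
gen_background <- function(n, fs, beta) {
  white <- stats::rnorm(n)
  if (beta == 0) {
    return(white / stats::sd(white))
  }
  xf <- stats::fft(white)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, n - k) / n * fs
  shape <- c(0, f[-1]^(-beta / 2))  # kill DC
  x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate an ECoG-like synthetic signal
#'
#' The background is `1/f^beta` Gaussian noise normalized to unit RMS (the
#' broadband spectrum typical of cortical recordings); each burst adds a
#' raised-cosine-enveloped sinusoid with a phase drawn uniformly. Identical
#' seeds give bit-identical output.
#'
#' @param fs Sampling rate in Hz; must be at least 4x the highest analysis
#'   frequency (64 Hz for the default 16 Hz grid top).
#' @param duration Signal length in seconds.
#' @param bursts A [burst_spec()] tibble (or `NULL` for pure background).
#'   Bursts must lie inside `[0, duration]`.
#' @param beta Background spectral exponent, in \[0, 2\].
#' @param seed Optional integer seed; the signal is a pure function of the
#'   arguments when set.
#' @param channel Channel label for the output series.
#' @param f_max Highest analysis frequency used for the `fs` precondition.
#' @return A list with `ts` (an [ecog_ts()]) and `truth` (the burst table
#'   with added `band` and `overlaps_in_band` columns).
#' @examples
#' sig <- gen_signal(100, 30, burst_spec(10, 2, 5.5), seed = 42)
#' sig$truth
#' @export
gen_signal <- function(fs, duration, bursts = NULL, beta = 1, seed = NULL,
                       channel = "sim", f_max = 16) {
  stopifnot(fs > 0, duration > 0, beta >= 0, beta <= 2)
  if (fs < 4 * f_max) {
    stop("fs must be at least 4 * f_max = ", 4 * f_max, " Hz", call. = FALSE)
  }
  if (!is.null(bursts) && nrow(bursts) > 0 &&
      any(bursts$t_start + bursts$duration > duration + 1e-9)) {
    stop("bursts must lie inside [0, duration]", call. = FALSE)
  }
  n <- round(duration * fs)
  with_seed(seed, {
    x <- gen_background(n, fs, beta)
    truth <- empty_truth()
    if (!is.null(bursts) && nrow(bursts) > 0) {
      tt <- (seq_len(n) - 1) / fs
      phases <- stats::runif(nrow(bursts), 0, 2 * pi)
      for (i in seq_len(nrow(bursts))) {
        b <- bursts[i, ]
        sel <- tt >= b$t_start & tt < b$t_start + b$duration
        u <- (tt[sel] - b$t_start) / b$duration
        env <- 0.5 * (1 - cos(2 * pi * u))
        x[sel] <- x[sel] +
          b$amplitude * env * sin(2 * pi * b$f0 * (tt[sel] - b$t_start) +
                                    phases[i])
      }
      truth <- flag_band_overlaps(bursts)
    }
    list(ts = ecog_ts(x, fs = fs, channel = channel), truth = truth)
  })
}

empty_truth <- function() {
  tibble::tibble(t_start = numeric(), duration = numeric(), f0 = numeric(),
                 amplitude = numeric(), band = integer(),
                 overlaps_in_band = logical())
}

# annotate each burst with its band and whether it overlaps another burst of
# the same band in time
flag_band_overlaps <- function(bursts, scheme = band_scheme()) {
  bursts$band <- bin_band(bursts$f0, scheme)
  n <- nrow(bursts)
  ov <- logical(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!is.na(bursts$band[i]) && !is.na(bursts$band[j]) &&
            bursts$band[i] == bursts$band[j] &&
            bursts$t_start[i] < bursts$t_start[j] + bursts$duration[j] &&
            bursts$t_start[j] < bursts$t_start[i] + bursts$duration[i]) {
          ov[i] <- TRUE
          ov[j] <- TRUE
        }
      }
    }
  }
  bursts$overlaps_in_band <- ov
  bursts
}
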