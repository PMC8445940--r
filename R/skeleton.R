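#' Extract per-time frequency-local maxima of the wavelet energy
#'
#' For each time column the frequency-local maxima of `E(., t)` above a noise
#' floor are returned. The floor is the `floor_quantile` quantile of all
#' COI-interior energies; it exists only to suppress numerically irrelevant
#' maxima on near-zero columns and is a nuisance parameter — detected
#' patterns are never ranked or filtered by amplitude beyond it. Points
#' inside the cone of influence (unreliable edge region) are discarded.
#' Plateau ties are resolved toward the lower frequency.
#'
#' @param spec A `cwt_spectrum` from [compute_cwt()].
#' @param floor_quantile Noise-floor quantile in `[0, 1)` of the interior
#'   energies (default 0.5).
#' @param max_ridges Maximum number of maxima kept per time column.
#' @param floor_mode `"global"` (default): one floor, the empirical
#'   `floor_quantile` quantile of all interior energies. `"robust"`: a
#'   scale-adaptive floor per frequency row, `median(row) * log2(1/(1-q))`
#'   — for a Gaussian background the per-scale energy is exponentially
#'   distributed, so this is the row's q-quantile under the background-only
#'   model, robust to contamination by strong transient bursts and to the
#'   1/f tilt of broadband noise. Use it at high quantiles (e.g. 0.99) when
#'   isolating bursts well above the background.
#' @return A tibble with columns `t_idx`, `time_s`, `f_idx`, `freq_hz`,
#'   `energy`, ordered by time then frequency. May have zero rows.
#' @export
extract_maxima <- function(spec, floor_quantile = 0.5, max_ridges = 5,
                           floor_mode = c("global", "robust")) {
  floor_mode <- match.arg(floor_mode)
  stopifnot(inherits(spec, "cwt_spectrum"),
            floor_quantile >= 0, floor_quantile < 1, max_ridges >= 1)
  e <- spec$energy
  nf <- nrow(e)
  ok <- coi_interior(spec)
  if (!any(ok)) {
    return(empty_maxima())
  }
  if (floor_mode == "global") {
    floor_e <- stats::quantile(e[ok], floor_quantile, names = FALSE)
  } else {
    # exponential-model quantile from the row median (robust to bursts);
    # rows entirely outside the COI get +Inf
    factor_q <- log2(1 / (1 - floor_quantile))
    floor_e <- numeric(nf)
    for (i in seq_len(nf)) {
      v <- e[i, ok[i, ]]
      floor_e[i] <- if (length(v)) stats::median(v) * factor_q else Inf
    }
  }
  # local maximum over frequency: strictly above the lower neighbour and at
  # least the upper one, so the lowest point of an exact plateau wins
  cand <- matrix(FALSE, nrow = nf, ncol = ncol(e))
  cand[2:(nf - 1), ] <- e[2:(nf - 1), ] > e[1:(nf - 2), ] &
    e[2:(nf - 1), ] >= e[3:nf, ]
  cand <- cand & ok & e > floor_e
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(empty_maxima())
  }
  en <- e[idx]
  # cap at max_ridges per column, keeping the strongest (ties: lower f);
  # the cap is a guard against pathological columns, not a ranking
  ord <- order(idx[, 2], -en, idx[, 1])
  col_sorted <- idx[ord, 2]
  rank_in_col <- sequence(rle(col_sorted)$lengths)
  keep <- ord[rank_in_col <= max_ridges]
  keep <- keep[order(idx[keep, 2], idx[keep, 1])]
  tibble::tibble(
    t_idx = unname(idx[keep, 2]),
    time_s = spec$times[idx[keep, 2]],
    f_idx = unname(idx[keep, 1]),
    freq_hz = spec$freqs[idx[keep, 1]],
    energy = en[keep]
  )
}

empty_maxima <- function() {
  tibble::tibble(t_idx = integer(), time_s = numeric(), f_idx = integer(),
                 freq_hz = numeric(), energy = numeric())
}

#' Link per-time maxima into skeleton lines
#'
#' Chains maxima of consecutive time columns into ridge ("skeleton") lines by
#' greedy nearest-frequency matching: among all (active line, new point)
#' pairs with frequency gap at most `link_tol`, the smallest gap is matched
#' first (ties toward the lower frequency). A line with no partner ends; an
#' unmatched point starts a new line; a missing time column ends every active
#' line, so lines are gap-free at the spectrum's time step. Every input point
#' belongs to exactly one line.
#'
#' @param maxima Tibble from [extract_maxima()].
#' @param link_tol Maximum frequency jump between consecutive columns, Hz.
#' @return The input tibble with a `line_id` column, ordered by `line_id`
#'   then time.
#' @export
link_maxima <- function(maxima, link_tol = 0.5) {
  stopifnot(is.data.frame(maxima), link_tol > 0)
  if (nrow(maxima) == 0L) {
    return(tibble::tibble(line_id = integer(), maxima))
  }
  m <- maxima[order(maxima$t_idx, maxima$f_idx), ]
  tcol <- m$t_idx
  freq <- m$freq_hz
  n <- nrow(m)
  line_id <- integer(n)
  runs <- rle(tcol)
  col_t <- runs$values
  col_end <- cumsum(runs$lengths)
  col_start <- col_end - runs$lengths + 1L
  next_id <- 1L
  act_f <- numeric(0)   # last frequency of each active line
  act_id <- integer(0)
  prev_t <- NA_integer_
  for (ci in seq_along(col_t)) {
    rows <- col_start[ci]:col_end[ci]
    fs_new <- freq[rows]
    k <- length(rows)
    if (!is.na(prev_t) && col_t[ci] != prev_t + 1L) {
      act_f <- numeric(0); act_id <- integer(0)
    }
    ids <- integer(k)
    na_act <- length(act_f)
    if (na_act == 1L && k == 1L) {
      if (abs(act_f - fs_new) <= link_tol) ids[1L] <- act_id
    } else if (na_act > 0L) {
      # all candidate pairs once, processed by increasing gap;
      # ties resolved toward lower frequencies
      gap <- abs(rep(act_f, times = k) - rep(fs_new, each = na_act))
      sel <- which(gap <= link_tol)
      if (length(sel)) {
        aa <- (sel - 1L) %% na_act + 1L
        bb <- (sel - 1L) %/% na_act + 1L
        used_a <- logical(na_act)
        used_n <- logical(k)
        for (p in order(gap[sel], fs_new[bb], act_f[aa])) {
          a <- aa[p]; b <- bb[p]
          if (!used_a[a] && !used_n[b]) {
            ids[b] <- act_id[a]
            used_a[a] <- TRUE
            used_n[b] <- TRUE
          }
        }
      }
    }
    fresh <- ids == 0L
    if (any(fresh)) {
      ids[fresh] <- next_id + seq_len(sum(fresh)) - 1L
      next_id <- next_id + sum(fresh)
    }
    line_id[rows] <- ids
    act_f <- fs_new
    act_id <- ids
    prev_t <- col_t[ci]
  }
  out <- tibble::tibble(line_id = line_id, m)
  out[order(out$line_id, out$t_idx), ]
}

#' Extract linked skeleton lines from a wavelet spectrum
#'
#' Convenience wrapper: [extract_maxima()] followed by [link_maxima()].
#'
#' @inheritParams extract_maxima
#' @inheritParams link_maxima
#' @return Tibble of skeleton points with `line_id` (see [link_maxima()]).
#' @export
skeleton_lines <- function(spec, floor_quantile = 0.5, max_ridges = 5,
                           link_tol = 0.5, floor_mode = "global") {
  link_maxima(extract_maxima(spec, floor_quantile, max_ridges, floor_mode),
              link_tol)
}
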