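test_that("a single tone yields exactly one maximum per interior column", {
  spec <- compute_cwt(make_tone(5, dur = 20))
  mx <- extract_maxima(spec)
  counts <- table(mx$t_idx)
  expect_true(all(counts == 1))
  expect_true(all(abs(mx$freq_hz - 5) < 0.2))
  # every interior column is represented
  interior <- which(spec$coi_hz <= 5)
  expect_setequal(unique(mx$t_idx), interior)
})

test_that("zero signal yields no maxima", {
  spec <- compute_cwt(ecog_ts(rep(0, 2000), fs = 100))
  expect_equal(nrow(extract_maxima(spec)), 0L)
})

test_that("two equal tones yield two maxima per interior column", {
  tt <- seq(0, 20 - 0.01, by = 0.01)
  ts <- ecog_ts(sin(2 * pi * 3 * tt) + sin(2 * pi * 10 * tt), fs = 100)
  mx <- extract_maxima(compute_cwt(ts))
  interior_cols <- mx$t_idx[mx$time_s > 2 & mx$time_s < 18]
  counts <- table(interior_cols)
  expect_true(all(counts == 2))
})

test_that("constant-frequency maxima chain into a single line", {
  cols <- tibble::tibble(t_idx = 1:100, time_s = (0:99) * 0.01,
                         f_idx = 81L, freq_hz = 5, energy = 1)
  lines <- link_maxima(cols)
  expect_equal(unique(lines$line_id), 1L)
  expect_equal(nrow(lines), 100L)
})

test_that("a slow chirp is tracked as one line; separated tones never merge", {
  tt <- seq(0, 30 - 0.01, by = 0.01)
  chirp <- sin(2 * pi * (3 * tt + 0.05 * tt^2))  # 3 -> 6 Hz over 30 s
  lines <- skeleton_lines(compute_cwt(ecog_ts(chirp, fs = 100)))
  main <- lines |> dplyr::count(line_id) |> dplyr::slice_max(n, n = 1)
  main_pts <- lines[lines$line_id == main$line_id, ]
  # one dominant line spanning nearly the whole interior, following the ramp
  expect_gt(nrow(main_pts), 2500)
  expect_lt(min(main_pts$freq_hz), 3.5)
  expect_gt(max(main_pts$freq_hz), 5.5)

  two <- ecog_ts(sin(2 * pi * 3 * tt) + sin(2 * pi * 10 * tt), fs = 100)
  lines2 <- skeleton_lines(compute_cwt(two))
  per_line_span <- tapply(lines2$freq_hz, lines2$line_id,
                          function(f) max(f) - min(f))
  expect_true(all(per_line_span < 2))  # no line bridges the 7 Hz gap
})

test_that("linking partitions the maxima exactly (no loss, no duplication)", {
  set.seed(11)
  for (i in 1:5) {
    sig <- gen_signal(100, 30, NULL, beta = 1, seed = 50 + i)
    mx <- extract_maxima(compute_cwt(sig$ts))
    lines <- link_maxima(mx)
    expect_equal(nrow(lines), nrow(mx))
    expect_equal(
      dplyr::arrange(lines[c("t_idx", "f_idx", "energy")], t_idx, f_idx),
      dplyr::arrange(mx[c("t_idx", "f_idx", "energy")], t_idx, f_idx)
    )
    expect_true(all(lines$line_id >= 1))
  }
})

test_that("raising the floor quantile never adds skeleton points", {
  sig <- gen_signal(100, 60, NULL, beta = 1, seed = 77)
  spec <- compute_cwt(sig$ts)
  n_prev <- Inf
  for (q in c(0.1, 0.5, 0.9, 0.99)) {
    n_q <- nrow(extract_maxima(spec, floor_quantile = q))
    expect_lte(n_q, n_prev)
    n_prev <- n_q
  }
})

test_that("equal-energy plateaus resolve toward the lower frequency", {
  spec <- compute_cwt(make_tone(5, dur = 10))
  # force an exact two-point plateau at the ridge of one column
  col <- 500
  fi <- which.max(spec$energy[, col])
  spec$energy[fi + 1, col] <- spec$energy[fi, col]
  mx <- extract_maxima(spec)
  got <- mx$f_idx[mx$t_idx == col]
  expect_equal(got, fi)
})

test_that("points inside the cone of influence are excluded", {
  spec <- compute_cwt(make_tone(1.2, dur = 20))
  mx <- extract_maxima(spec)
  # default COI at 1.2 Hz: 2*sqrt(2)/1.2 = 2.36 s from each edge
  expect_true(all(mx$freq_hz >= spec$coi_hz[mx$t_idx]))
  expect_gt(min(mx$time_s[abs(mx$freq_hz - 1.2) < 0.1]), 2.0)
})

test_that("the robust floor mode suppresses background but keeps bursts", {
  sig <- gen_signal(100, 60, burst_spec(30, 2, 5.5, 5), seed = 13)
  spec <- compute_cwt(sig$ts)
  mx_robust <- extract_maxima(spec, 0.9999, floor_mode = "robust")
  mx_default <- extract_maxima(spec, 0.5)
  expect_lt(nrow(mx_robust), nrow(mx_default) / 10)
  expect_true(any(abs(mx_robust$freq_hz - 5.5) < 0.3 &
                    abs(mx_robust$time_s - 31) < 1))
})
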