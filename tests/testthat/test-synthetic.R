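test_that("generation is a pure function of the seed", {
  s1 <- gen_signal(100, 10, burst_spec(3, 2, 5, 4), seed = 12)
  s2 <- gen_signal(100, 10, burst_spec(3, 2, 5, 4), seed = 12)
  expect_identical(s1$ts$samples, s2$ts$samples)
  s3 <- gen_signal(100, 10, burst_spec(3, 2, 5, 4), seed = 13)
  expect_false(identical(s1$ts$samples, s3$ts$samples))
  # the generator does not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(gen_signal(100, 5, NULL, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("burst specifications enforce their invariants", {
  expect_error(burst_spec(0, 0.3, 5), "two periods")
  expect_error(burst_spec(0, 2, 0.3), "\\[0.5, 16\\]")
  expect_error(burst_spec(0, 2, 17), "\\[0.5, 16\\]")
  expect_error(burst_spec(-1, 2, 5), "t_start")
  expect_error(gen_signal(100, 10, burst_spec(9, 2, 5)), "inside")
  expect_error(gen_signal(50, 10, NULL), "4 \\* f_max")
})

test_that("the background has unit RMS and a 1/f-type spectrum", {
  sig <- gen_signal(100, 120, NULL, beta = 1, seed = 3)
  x <- sig$ts$samples
  expect_equal(stats::sd(x), 1, tolerance = 1e-12)
  # low-frequency band must carry more power than an equal-width high band
  sp <- stats::spec.pgram(stats::ts(x, frequency = 100), plot = FALSE,
                          spans = 31)
  lo <- mean(sp$spec[sp$freq > 1 & sp$freq < 4])
  hi <- mean(sp$spec[sp$freq > 10 & sp$freq < 13])
  expect_gt(lo / hi, 3)
})

test_that("a single synthetic burst is recovered end to end", {
  sig <- gen_signal(100, 30, burst_spec(10, 2, 5.5, amplitude = 5), seed = 42)
  expect_equal(sig$truth$band, 3L)
  pats <- detect_patterns(sig$ts, settings = settings_burst_isolation())
  inb <- pats[!is.na(pats$band), ]
  expect_equal(nrow(inb), 1L)
  expect_equal(inb$band, 3L)
  expect_lt(abs(inb$f_mean - 5.5), 0.3)
  # detected ridge duration lies between the envelope FWHM and full support
  expect_gte(inb$duration_s, 1.0)
  expect_lte(inb$duration_s, 2.0 + 0.1)
})

test_that("same-band overlaps are flagged in the ground truth", {
  b <- burst_spec(c(0, 1, 10), c(2, 2, 2), c(5, 5.2, 5.1), 4)
  sig <- gen_signal(100, 20, b, seed = 2)
  expect_equal(sig$truth$overlaps_in_band, c(TRUE, TRUE, FALSE))
})

test_that("a cohort is reproducible and shaped by its specification", {
  c1 <- gen_cohort(n_subjects = 2, episode_s = 20, n_episodes = 1, seed = 6)
  c2 <- gen_cohort(n_subjects = 2, episode_s = 20, n_episodes = 1, seed = 6)
  expect_identical(c1$series[[1]]$samples, c2$series[[1]]$samples)
  expect_identical(c1$truth[[4]], c2$truth[[4]])
  expect_equal(nrow(c1), 6L)  # 2 subjects x 3 recordings
  expect_setequal(unique(c1$recording_id), c("ECoG1", "ECoG2", "ECoG3"))
  ann <- c1$annotations[[1]]
  expect_equal(ann$state, c("awake", "sleep"))
  expect_equal(ts_duration(c1$series[[1]]), 40)
  # empty cohort
  c0 <- gen_cohort(n_subjects = 0)
  expect_equal(nrow(c0), 0L)
})

test_that("detected per-band rates track the resolvable event rate", {
  # calibration: 600 s at 6 bursts/min/band, 6-10-cycle bursts, SNR 5;
  # bursts whose half-maximum envelopes overlap count as one event
  for (seed in c(101, 202)) {
    set.seed(seed)
    bursts <- oscipat:::draw_episode_bursts(600, rep(6, 6), 5, c(6, 10),
                                            band_scheme())
    sig <- gen_signal(100, 600, bursts, seed = seed + 1)
    pats <- detect_patterns(sig$ts, settings = settings_burst_isolation())
    detected <- as.numeric(table(factor(pats$band, levels = 1:6)))
    events <- resolvable_events(bursts)
    expect_true(all(abs(detected / events - 1) < 0.2),
                info = paste("seed", seed, ":",
                             paste(round(detected / events, 3),
                                   collapse = " ")))
  }
})
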