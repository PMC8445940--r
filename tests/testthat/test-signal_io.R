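test_that("one-column CSV with fs_override gives the right duration", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("value", format(sin(1:1000 / 50))), p)
  ts <- read_timeseries(p, fs_override = 100)
  expect_s3_class(ts, "ecog_ts")
  expect_equal(ts_duration(ts), 10.0)
  expect_error(read_timeseries(p), "fs_override")
})

test_that("two-column CSV reads and rejects non-uniform time grids", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time_s = seq(0, 0.99, by = 0.01), value = rnorm(100))
  utils::write.csv(df, p, row.names = FALSE)
  ts <- read_timeseries(p)
  expect_equal(ts$fs, 100, tolerance = 1e-9)
  expect_equal(length(ts$samples), 100L)

  bad <- data.frame(time_s = c(0, 0.01, 0.03, 0.04), value = 1:4)
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(read_timeseries(p), "non-uniform")
})

test_that("CSV round-trip is bit-exact in samples and ~exact in fs", {
  ts <- ecog_ts(rnorm(257, sd = 13.7), fs = 250, channel = "FrL", t0 = 2.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(ts, p)
  back <- read_timeseries(p, channel = "FrL")
  expect_identical(back$samples, ts$samples)
  expect_equal(back$fs, ts$fs, tolerance = 1e-9)
  expect_equal(back$t0, ts$t0, tolerance = 1e-9)
})

test_that("EDF files round-trip through the 16-bit reader", {
  p <- withr::local_tempfile(fileext = ".edf")
  fs <- 100
  sig1 <- sin(2 * pi * 5 * (0:999) / fs) * 40
  sig2 <- cos(2 * pi * 2 * (0:999) / fs) * 25
  oscipat:::write_edf_minimal(p, list(FrL = sig1, OcR = sig2), fs = fs)
  ts <- read_timeseries(p, channel = "OcR")
  expect_equal(ts$channel, "OcR")
  expect_equal(ts$fs, fs)
  expect_equal(length(ts$samples), 1000L)
  # 16-bit quantization over a +/-40 range: ~1.2e-3 absolute
  expect_lt(max(abs(ts$samples - sig2)), 40 / 32767 * 2)
  expect_error(read_timeseries(p, channel = "Cz"), "not found")
  expect_error(read_timeseries(sub("edf$", "xyz", p)), "")
})

test_that("unknown formats are rejected", {
  p <- withr::local_tempfile(fileext = ".bin")
  writeLines("junk", p)
  expect_error(read_timeseries(p), "unknown signal format")
  expect_error(read_timeseries("/nonexistent/file.csv"), "not found")
})

test_that("split_episodes bisects a tiled recording exactly", {
  ts <- ecog_ts(rnorm(6000), fs = 100)
  ann <- tibble::tibble(start_s = c(0, 30), end_s = c(30, 60),
                        state = c("awake", "sleep"))
  eps <- split_episodes(ts, ann, "ECoG1", "rat1")
  expect_equal(nrow(eps), 2L)
  expect_equal(eps$duration_s, c(30, 30))
  expect_equal(eps$state, c("awake", "sleep"))
  # half-open cut: no sample is in two episodes, and all samples are used
  expect_equal(sum(vapply(eps$series, function(s) length(s$samples), 1L)),
               6000L)
  expect_equal(eps$series[[2]]$t0, 30)
})

test_that("split_episodes rejects intervals outside the recording", {
  ts <- ecog_ts(rnorm(6000), fs = 100)
  ann <- tibble::tibble(start_s = 0, end_s = 70, state = "awake")
  expect_error(split_episodes(ts, ann), "outside the recording")
})

test_that("empty annotations yield an empty episode table", {
  ts <- ecog_ts(rnorm(100), fs = 100)
  ann <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                        state = character())
  eps <- split_episodes(ts, ann)
  expect_equal(nrow(eps), 0L)
})

test_that("annotation validation enforces order, overlap and labels", {
  expect_error(validate_annotations(
    tibble::tibble(start_s = 5, end_s = 5, state = "awake")), "start_s <")
  expect_error(validate_annotations(
    tibble::tibble(start_s = c(0, 5), end_s = c(10, 15),
                   state = c("awake", "sleep"))), "overlap")
  expect_error(validate_annotations(
    tibble::tibble(start_s = 0, end_s = 10, state = "rem")), "unknown state")
  # shared boundary is not an overlap (half-open intervals)
  ok <- validate_annotations(
    tibble::tibble(start_s = c(10, 0), end_s = c(20, 10),
                   state = c("sleep", "awake")))
  expect_equal(ok$start_s, c(0, 10))
})

test_that("episode durations never exceed the recording, with equality on tiling", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(2000:4000, 1)
    ts <- ecog_ts(rnorm(n), fs = 100)
    dur <- ts_duration(ts)
    cuts <- sort(stats::runif(3, 1, dur - 1))
    ann <- tibble::tibble(
      start_s = c(0, cuts), end_s = c(cuts, dur),
      state = rep_len(c("awake", "sleep"), 4))
    eps <- split_episodes(ts, ann)
    total <- sum(vapply(eps$series, ts_duration, 1))
    expect_lte(total, dur + 1e-9)
    expect_equal(total, dur, tolerance = 1e-9)  # annotations tile exactly
  }
})
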