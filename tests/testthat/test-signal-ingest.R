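test_that("R-peak detection recovers planted beats on clean synthetic ECG", {
  rr <- regular_rr(1000, 60)
  ecg <- gen_ecg(rr, sampling_rate = 250)
  planted <- attr(ecg, "beat_times")
  peaks <- detect_r_peaks(ecg)
  expect_length(peaks, length(planted))
  err_s <- vapply(planted, function(b) min(abs(peaks - b)), numeric(1))
  expect_lte(max(err_s), 1 / 250 + 1e-9)
  gaps <- diff(peaks) * 1000
  expect_true(all(abs(gaps - 1000) <= 4 + 1e-9))  # 1 sample at 250 Hz
})

test_that("R-peak detection stays accurate under additive noise", {
  rr <- regular_rr(1000, 60)
  planted <- NULL
  stats <- sapply(1:10, function(s) {
    ecg <- gen_ecg(rr, sampling_rate = 250, snr_db = 20, seed = s)
    planted <<- attr(ecg, "beat_times")
    match_peaks(detect_r_peaks(ecg), planted, tol = 1 / 250 + 1e-9)
  })
  expect_gte(mean(stats["recall", ]), 0.995)
  expect_gte(mean(stats["precision", ]), 0.995)
})

test_that("degenerate traces are rejected with informative errors", {
  expect_error(detect_r_peaks(ecg_trace(rep(0, 5000), 250)), "no QRS")
  expect_error(detect_r_peaks(ecg_trace(c(0, 1), 250)), "insufficient signal")
  expect_error(ecg_trace(c(0, NA), 250), "finite")
  expect_error(ecg_trace(numeric(1), 250), "at least 2")
})

test_that("rr_from_peaks differences peak times into ms intervals", {
  rr <- rr_from_peaks(c(0.0, 1.0, 2.01))
  expect_equal(rr$intervals, c(1000, 1010))
  expect_equal(rr$beat_times, c(1.0, 2.01))
  expect_equal(rr_from_peaks(c(0, 1))$intervals, 1000)
  expect_error(rr_from_peaks(c(1, 1, 2)), "strictly increasing")
  expect_error(rr_from_peaks(2), "at least 2")
})

test_that("detection plus differencing recovers planted intervals", {
  set.seed(11)
  iv <- rnorm(80, 900, 40)
  rr0 <- rri_series(cumsum(iv) / 1000, iv)
  ecg <- gen_ecg(rr0, sampling_rate = 250)
  rr1 <- rr_from_peaks(detect_r_peaks(ecg))
  # one planted beat opens the first interval, so counts line up exactly
  expect_equal(length(rr1$intervals), length(rr0$intervals))
  # planted intervals recovered to within one sample period (4 ms)
  expect_lte(max(abs(rr1$intervals - rr0$intervals)), 4 + 1e-9)
})

test_that("artifact filter drops out-of-bounds and jump intervals only", {
  rr <- rri_series(1:4, c(1000, 1005, 4000, 998))
  out <- clean_rr(rr)
  expect_equal(out$intervals, c(1000, 1005, 998))
  expect_equal(attr(out, "n_removed"), 1L)

  rr2 <- rri_series(1:4, c(1000, 1000, 1500, 1000))
  out2 <- clean_rr(rr2, jump_fraction = 0.2)
  expect_equal(out2$intervals, c(1000, 1000, 1000))

  smooth <- rri_series(1:5, c(900, 920, 940, 930, 910))
  expect_equal(clean_rr(smooth)$intervals, smooth$intervals)
  expect_equal(attr(clean_rr(smooth), "n_removed"), 0L)

  expect_error(clean_rr(rri_series(1:2, c(2500, 2600))), "no usable beats")
})

test_that("cleaning yields a subsequence and never adds intervals", {
  set.seed(4)
  for (rep in 1:20) {
    iv <- sample(c(rnorm(40, 1000, 60), runif(5, 2100, 5000)))
    rr <- rri_series(cumsum(iv) / 1000, iv)
    out <- clean_rr(rr)
    expect_lte(length(out$intervals), length(rr$intervals))
    # subsequence check: retained (time, interval) pairs appear in order
    idx <- match(out$beat_times, rr$beat_times)
    expect_false(any(is.na(idx)))
    expect_true(all(diff(idx) > 0))
    expect_equal(out$intervals, rr$intervals[idx])
  }
})

test_that("excitement trim keeps the inner span and validates duration", {
  tt <- seq(0, 7000, by = 10)
  prof <- altitude_profile(tt, 4000 + sin(tt / 500) * 100)
  out <- trim_excitement(prof)
  expect_equal(range(out$times), c(1000, 6000))

  expect_equal(trim_excitement(prof, 0, 0)$times, prof$times)
  # idempotent once trimmed with zero margins
  expect_equal(trim_excitement(out, 0, 0)$times, out$times)

  short <- altitude_profile(seq(0, 1500, 10), rep(4000, 151))
  expect_error(trim_excitement(short), "trim exceeds recording")
})

test_that("blink frequency counts per window in times/min", {
  b <- blink_series(seq(2, 118, length.out = 30))
  expect_equal(blink_frequency(b, cbind(0, 120)), 15)
  expect_equal(blink_frequency(blink_series(numeric(0)), cbind(0, 60)), 0)
  # simultaneous blinks each count; nondecreasing is allowed
  expect_equal(blink_frequency(blink_series(c(10, 10, 10)), cbind(0, 60)), 3)
  expect_error(blink_frequency(b, cbind(10, 10)), "zero-length")
  expect_error(blink_frequency(b, rbind(c(0, 60), c(30, 90))),
               "non-overlapping")
})

test_that("blink counts are conserved over a partition of the span", {
  set.seed(9)
  for (rep in 1:10) {
    b <- blink_series(sort(runif(200, 0, 600)))
    cuts <- sort(runif(4, 1, 599))
    w <- cbind(c(0, cuts), c(cuts, 600.001))
    rates <- blink_frequency(b, w)
    counts <- rates * (w[, 2] - w[, 1]) / 60
    expect_equal(sum(counts), 200)
  }
})

test_that("CSV round trips preserve each series", {
  td <- withr::local_tempdir()
  rr <- regular_rr(950, 20)
  write.csv(data.frame(time_s = rr$beat_times, rr_ms = rr$intervals),
            file.path(td, "rr.csv"), row.names = FALSE)
  rr2 <- read_rr_csv(file.path(td, "rr.csv"))
  expect_equal(rr2$intervals, rr$intervals)

  prof <- gen_altitude_profile(c(0, 100), c(3540, 3600), dt = 25)
  write.csv(data.frame(time_s = prof$times, altitude_m = prof$altitudes),
            file.path(td, "alt.csv"), row.names = FALSE)
  expect_equal(read_altitude_csv(file.path(td, "alt.csv"))$altitudes,
               prof$altitudes)

  write.csv(data.frame(blink_time_s = c(1, 2.5, 7)),
            file.path(td, "blink.csv"), row.names = FALSE)
  expect_equal(read_blink_csv(file.path(td, "blink.csv"))$blink_times,
               c(1, 2.5, 7))

  expect_error(read_rr_csv(file.path(td, "alt.csv")), "time_s, rr_ms")
})
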