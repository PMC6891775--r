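test_that("windowed HRV statistics match the direct formulas", {
  rr <- rri_series(c(1, 2.01, 3.0, 4.005, 5.01),
                   c(1000, 1010, 990, 1005, 1005))
  w <- window_hrv(rr, window_length = 4.5, min_beats = 4, origin = 0)
  expect_equal(nrow(w), 2L)
  expect_false(w$usable[2])  # trailing single-beat window is flagged
  expect_equal(w$M[1], 1001.25)
  expect_equal(w$SDNN[1], sd(c(1000, 1010, 990, 1005)))
  expect_equal(w$SDNN[1], 8.53912, tolerance = 1e-6)
  expect_equal(w$RRVC[1], w$SDNN[1] / w$M[1])
  expect_equal(w$RRVC[1], 0.008529, tolerance = 1e-4)
})

test_that("constant intervals give zero SDNN and RRVC", {
  rr <- regular_rr(1000, 200)
  w <- window_hrv(rr, 60)
  expect_true(all(w$SDNN == 0))
  expect_true(all(w$RRVC == 0))
})

test_that("windows partition the beats with each interval counted once", {
  rr <- regular_rr(1000, 600)
  w <- window_hrv(rr, 120)
  expect_equal(nrow(w), 5L)
  expect_equal(sum(w$n_beats), length(rr$intervals))
  expect_equal(w$end - w$start, rep(120, 5))
})

test_that("windowed statistics equal a brute-force oracle on random series", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(200:500, 1)
    iv <- runif(n, 600, 1200)
    rr <- rri_series(cumsum(iv) / 1000, iv)
    L <- sample(c(30, 60, 120), 1)
    w <- window_hrv(rr, L, min_beats = 2)
    orc <- oracle_windows(rr, L)
    ok <- orc$n >= 2
    expect_equal(w$M[ok], orc$M[ok], tolerance = 1e-12)
    expect_equal(w$SDNN[ok], orc$SDNN[ok], tolerance = 1e-12)
    expect_equal(w$RRVC[ok], orc$SDNN[ok] / orc$M[ok], tolerance = 1e-12)
  }
})

test_that("compute_rrvc is the guarded ratio SDNN/M", {
  expect_equal(compute_rrvc(50, 1000), 0.05)
  expect_equal(compute_rrvc(0, 800), 0)
  expect_equal(compute_rrvc(8.539, 1001.25), 8.539 / 1001.25)
  expect_error(compute_rrvc(10, 0), "positive")
  expect_error(compute_rrvc(-1, 1000), "nonnegative")
})

test_that("baselines difference the initial and static variation", {
  rr <- regular_rr(1000, 900)
  # plant window RRVCs by hand through a synthetic windows table
  w <- window_hrv(rri_series(cumsum(runif(600, 0.8, 1.2)),
                             runif(600, 800, 1200)), 60, min_beats = 2)
  w$RRVC <- seq(0.05, by = 0.02, length.out = nrow(w))
  bl <- compute_baselines(w, rrvc_static = 0.03, k = 1)
  expect_equal(bl$rrvc_initial, 0.05)
  expect_equal(bl$bdf, 0.02)
  bl2 <- compute_baselines(w, rrvc_static = 0.03, k = 2)
  expect_equal(bl2$rrvc_initial, 0.06)
  expect_error(compute_baselines(w, rrvc_static = 0.05, k = 1),
               "degenerate baseline")
})

test_that("static baseline aggregates the whole rest recording", {
  set.seed(3)
  iv <- rnorm(300, 1000, 30)
  static <- rri_series(cumsum(iv) / 1000, iv)
  w <- window_hrv(regular_rr(1000, 300), 60)
  w$RRVC[1] <- 0.08
  bl <- compute_baselines(w, static_rr = static)
  expect_equal(bl$rrvc_static, sd(iv) / mean(iv))
})

test_that("fatigue metrics obey the defining identities", {
  w <- window_hrv(regular_rr(1000, 900), 120)
  w$RRVC <- c(0.05, 0.07, 0.09, 0.06, 0.085, 0.11, 0.12,
              0.095)[seq_len(nrow(w))]
  bl <- compute_baselines(w, rrvc_static = 0.03)
  fm <- compute_fatigue_metrics(w, bl)
  tab <- fm$table
  # worked examples of the definition
  expect_equal(tab$DFD[tab$RRVC == 0.07], 1.0)
  expect_equal(tab$DFD[tab$RRVC == 0.09], 2.0)
  expect_equal(tab$DFD[tab$RRVC == 0.05], 0.0)
  # FC - DFC = BDF and DFD * BDF = DFC, all windows, machine precision
  expect_equal(tab$FC - tab$DFC, rep(bl$bdf, nrow(tab)), tolerance = 1e-12)
  expect_equal(tab$DFD * bl$bdf, tab$DFC, tolerance = 1e-12)
  expect_equal(fm$dfd$values, tab$DFD)
})

test_that("fatigue degree is invariant under uniform interval rescaling", {
  set.seed(31)
  for (rep in 1:10) {
    iv <- rnorm(800, 1000, 20 + 60 * seq(0, 1, length.out = 800))
    iv <- pmax(iv, 400)
    c_scale <- runif(1, 0.5, 2)
    rr1 <- rri_series(cumsum(iv) / 1000, iv)
    rr2 <- rri_series(cumsum(iv * c_scale) / 1000, iv * c_scale)
    w1 <- window_hrv(rr1, 60, origin = 0)
    w2 <- window_hrv(rr2, 60 * c_scale, origin = 0)
    # same beats fall in the rescaled windows, so RRVC per window is equal
    expect_equal(w2$RRVC, w1$RRVC, tolerance = 1e-12)
    d1 <- compute_fatigue_metrics(
      w1, compute_baselines(w1, rrvc_static = 0.01))$dfd
    d2 <- compute_fatigue_metrics(
      w2, compute_baselines(w2, rrvc_static = 0.01))$dfd
    expect_equal(d2$values, d1$values, tolerance = 1e-10)
  }
})

test_that("fatigue degree increases strictly with the window RRVC", {
  w <- window_hrv(regular_rr(1000, 900), 120)
  w$RRVC <- sort(runif(nrow(w), 0.04, 0.2))
  bl <- compute_baselines(w, rrvc_static = 0.03)
  fm <- compute_fatigue_metrics(w, bl)
  expect_true(all(diff(fm$table$DFD[order(fm$table$RRVC)]) > 0))
})

test_that("cohort averaging combines the HRV parameters, not the ratios", {
  w1 <- window_hrv(regular_rr(800, 900), 120)
  w2 <- window_hrv(regular_rr(1200, 600, t0 = 0.4), 120, origin = 0.8)
  w1$SDNN <- rep(40, nrow(w1)); w1$M <- rep(800, nrow(w1))
  w2$SDNN <- rep(60, nrow(w2)); w2$M <- rep(1200, nrow(w2))
  w1$RRVC <- w1$SDNN / w1$M; w2$RRVC <- w2$SDNN / w2$M
  avg <- cohort_average(list(w1, w2))
  common <- seq_len(min(nrow(w1), nrow(w2)))
  expect_equal(avg$SDNN[common], rep(50, length(common)))
  expect_equal(avg$M[common], rep(1000, length(common)))
  expect_equal(avg$RRVC[common], rep(0.05, length(common)))
  expect_true(all(avg$n_drivers[common] == 2))
  # windows covered by one driver only average that driver
  if (nrow(avg) > length(common))
    expect_true(all(avg$n_drivers[-common] == 1))
  # single driver in, identical table out
  one <- cohort_average(list(w1))
  expect_equal(one$RRVC, w1$RRVC)
  expect_error(cohort_average(list()), "empty")
})

test_that("blink fatigue mirrors the HRV definition with blink baselines", {
  bl <- list(bf_static = 10, bf_initial = 15)
  out <- blink_dfd(c(15, 20, 25), t = c(60, 180, 300), baselines = bl)
  expect_equal(out$values, c(0, 1, 2))
  expect_equal(out$source, "blink")
  expect_error(blink_dfd(c(15, 20), c(60, 180),
                         list(bf_static = 15, bf_initial = 15)),
               "degenerate blink baseline")
})
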