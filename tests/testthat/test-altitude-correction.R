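test_that("slope classification labels monotone and mixed profiles", {
  up <- gen_altitude_profile(c(0, 3600), c(3540, 4768))
  seg <- classify_slope(up)
  expect_equal(seg$slope_class, "up")
  expect_equal(c(seg$start, seg$end), c(0, 3600))

  flat <- altitude_profile(seq(0, 3600, 10), rep(4200, 361))
  expect_equal(classify_slope(flat)$slope_class, "flat")

  # climb to the pass, descend, climb again
  mixed <- gen_altitude_profile(c(0, 3000, 5000, 7000),
                                c(3540, 4768, 4476, 4663))
  segm <- classify_slope(mixed)
  expect_equal(segm$slope_class, c("up", "down", "up"))
  # the segments partition the span
  expect_equal(segm$start[1], 0)
  expect_equal(segm$end[nrow(segm)], 7000)
  expect_equal(segm$start[-1], segm$end[-nrow(segm)])
})

test_that("short undulations merge into their neighbours", {
  tt <- seq(0, 4000, 10)
  h <- 3600 + 0.3 * tt
  h[tt >= 2000 & tt < 2100] <- h[tt >= 2000 & tt < 2100] - 5  # 100-s dip
  seg <- classify_slope(altitude_profile(tt, h))
  expect_equal(seg$slope_class, "up")
})

test_that("slope lookup maps window times to their segment class", {
  mixed <- gen_altitude_profile(c(0, 3000, 5000, 7000),
                                c(3540, 4768, 4476, 4663))
  seg <- classify_slope(mixed)
  cls <- slope_class_at(seg, c(1000, 4000, 6500))
  expect_equal(cls, c("up", "down", "up"))
  expect_true(is.na(slope_class_at(seg, -5)))
})

test_that("pointwise delta is the guarded ratio on the common grid", {
  tt <- seq(60, 1500, by = 120)
  hrv <- dfd_series(tt, rep(1, length(tt)), "hrv", 120)
  blink <- dfd_series(tt, rep(2, length(tt)), "blink", 120)
  h <- seq(3600, 4600, length.out = length(tt))
  pr <- pointwise_delta(blink, hrv, h)
  expect_equal(pr$delta, rep(2, length(tt)))
  expect_equal(pr$h, h)
  expect_equal(attr(pr, "n_excluded"), 0L)

  # identical series give delta = 1 everywhere
  pr1 <- pointwise_delta(hrv, hrv, h)
  expect_true(all(pr1$delta == 1))

  # windows near the HRV zero crossing are excluded and counted
  hrv2 <- hrv; hrv2$values[3] <- 0.01
  pr2 <- pointwise_delta(blink, hrv2, h, epsilon = 0.05)
  expect_equal(attr(pr2, "n_excluded"), 1L)
  expect_false(tt[3] %in% pr2$t)

  few <- dfd_series(tt[1:5], rep(0.01, 5), "hrv", 120)
  expect_error(pointwise_delta(dfd_series(tt[1:5], 1:5, "blink", 120),
                               few, h[1:5]),
               "insufficient calibration support")
})

test_that("calibration recovers a planted cubic exactly from clean pairs", {
  ref <- delta_reference("up")
  h <- seq(3540, 4768, length.out = 80)
  pairs <- data.frame(h = h,
                      delta = evaluate_delta(ref, h,
                                             warn_extrapolation = FALSE))
  m <- calibrate_delta(pairs, "up")
  expect_equal(m$coef, ref$coef, tolerance = 1e-6)
  expect_equal(m$h_range, c(3540, 4768))

  expect_error(calibrate_delta(data.frame(h = rep(4000, 10),
                                          delta = rep(1, 10)), "up"),
               "span too narrow")
})

test_that("calibration tracks the planted factor under multiplicative noise", {
  ref <- delta_reference("up")
  h <- seq(3540, 4768, length.out = 100)
  d0 <- evaluate_delta(ref, h, warn_extrapolation = FALSE)
  set.seed(1)
  m <- calibrate_delta(data.frame(h = h, delta = d0 * (1 + rnorm(100, 0, 0.05))),
                       "up")
  rel <- abs(evaluate_delta(m, h, warn_extrapolation = FALSE) / d0 - 1)
  expect_lte(max(rel), 0.05)
  # weighting handles zero-valued pairs without blowing up
  d2 <- d0; d2[c(3, 50)] <- 0
  m2 <- calibrate_delta(data.frame(h = h, delta = d2), "up")
  expect_true(all(is.finite(m2$coef)))
})

test_that("published correction factors evaluate to their printed values", {
  up <- delta_reference("up"); down <- delta_reference("down")
  expect_equal(evaluate_delta(up, 0, warn_extrapolation = FALSE), 366.711)
  expect_equal(evaluate_delta(down, 0, warn_extrapolation = FALSE), 493.703)
  expect_equal(evaluate_delta(up, 4000, warn_extrapolation = FALSE), 4.375,
               tolerance = 1e-12)
  expect_warning(evaluate_delta(up, 1000), "outside")
})

test_that("Horner evaluation agrees with naive term-by-term summation", {
  for (cls in c("up", "down")) {
    m <- delta_reference(cls)
    h <- seq(3540, 4768, length.out = 50)
    naive <- m$coef[1] + m$coef[2] * h + m$coef[3] * h^2 + m$coef[4] * h^3
    expect_equal(evaluate_delta(m, h, warn_extrapolation = FALSE), naive,
                 tolerance = 1e-9)
  }
})

test_that("revision multiplies the fatigue series by delta(h)", {
  tt <- seq(60, 1500, by = 120)
  hrv <- dfd_series(tt, seq(0, 3, length.out = length(tt)), "hrv", 120)
  h <- seq(3600, 4600, length.out = length(tt))

  ident <- structure(list(slope_class = "up", coef = c(1, 0, 0, 0),
                          h_range = c(0, 9000)), class = "delta_model")
  expect_equal(revise_dfd(hrv, ident, h)$values, hrv$values)

  twice <- structure(list(slope_class = "up", coef = c(2, 0, 0, 0),
                          h_range = c(0, 9000)), class = "delta_model")
  out <- revise_dfd(hrv, twice, h)
  expect_equal(out$values, 2 * hrv$values)
  expect_equal(out$source, "revised")
  # zeros are preserved for any correction
  expect_equal(out$values[hrv$values == 0], numeric(1))
  # homogeneity: scaling the fatigue series scales the revision
  hrv3 <- dfd_series(tt, 3 * hrv$values, "hrv", 120)
  expect_equal(revise_dfd(hrv3, twice, h)$values, 3 * out$values)
})

test_that("per-class revision uses each window's slope model", {
  mixed <- gen_altitude_profile(c(0, 3000, 5000, 7000),
                                c(3540, 4768, 4476, 4663))
  seg <- classify_slope(mixed)
  tt <- seq(1060, 5980, by = 120)
  hrv <- dfd_series(tt, rep(1, length(tt)), "hrv", 120)
  h <- altitude_at(mixed, tt)
  models <- list(
    up = structure(list(slope_class = "up", coef = c(2, 0, 0, 0),
                        h_range = c(0, 9000)), class = "delta_model"),
    down = structure(list(slope_class = "down", coef = c(3, 0, 0, 0),
                          h_range = c(0, 9000)), class = "delta_model"))
  out <- revise_dfd(hrv, models, h, segments = seg)
  cls <- slope_class_at(seg, tt)
  expect_equal(out$values[cls == "up"], rep(2, sum(cls == "up")))
  expect_equal(out$values[cls == "down"], rep(3, sum(cls == "down")))
  expect_error(revise_dfd(hrv, models["down"], h, segments = seg),
               "no correction model")
})

test_that("curve agreement reports SS, F and R2 on the joined grid", {
  tt <- seq(60, 6000, by = 120)
  set.seed(8)
  a <- dfd_series(tt, cumsum(runif(length(tt))), "hrv", 120)
  same <- curve_agreement(a, a)
  expect_equal(same$ss, 0)
  expect_equal(same$r2, 1)

  b <- dfd_series(tt, 2 * a$values + 1, "blink", 120)
  aff <- curve_agreement(a, b)
  expect_equal(aff$r2, 1)
  expect_equal(aff$ss, sum((a$values + 1)^2))

  expect_error(curve_agreement(
    dfd_series(1:3, 1:3, "hrv"), dfd_series(4:6, 1:3, "blink")),
    "common windows")
})

test_that("independent noise series show no curve agreement", {
  tt <- seq(60, 6000, length.out = 50)
  stats <- sapply(1:100, function(seed) {
    set.seed(seed)
    a <- dfd_series(tt, rnorm(50), "hrv", 120)
    b <- dfd_series(tt, rnorm(50), "blink", 120)
    ca <- curve_agreement(a, b)
    c(r2 = ca$r2, sig = ca$sig_F)
  })
  expect_lt(mean(stats["r2", ]), 0.1)
  expect_gte(mean(stats["sig", ] > 0.05), 0.9)
})

test_that("flat segments pass the altitude-independence check", {
  h <- seq(4400, 4550, length.out = 40)
  keep <- sapply(1:100, function(seed) {
    set.seed(seed)
    chk <- flat_segment_check(data.frame(h = h, delta = 1 + rnorm(40, 0, 0.1)))
    chk$sig_F >= 0.05
  })
  expect_gte(mean(keep), 0.9)

  # a genuinely altitude-dependent factor is detected
  dep <- flat_segment_check(data.frame(h = h, delta = 1 + 0.01 * (h - 4400)))
  expect_lt(dep$sig_F, 1e-6)
  expect_false(dep$altitude_independent)

  # constant factor: zero slope, F = 0
  const <- flat_segment_check(data.frame(h = h, delta = rep(1, 40)))
  expect_equal(const$slope, 0)
  expect_equal(const$F, 0)
  expect_error(flat_segment_check(data.frame(h = rep(4500, 10),
                                             delta = rnorm(10))),
               "degenerate")
})

test_that("correction models survive a JSON round trip", {
  td <- withr::local_tempdir()
  ref <- delta_reference("down")
  p <- file.path(td, "model.json")
  write_delta_model(ref, p)
  back <- read_delta_model(p)
  expect_equal(back$coef, ref$coef)
  expect_equal(back$slope_class, "down")
  expect_equal(back$h_range, ref$h_range)
  expect_equal(evaluate_delta(back, 4000, warn_extrapolation = FALSE),
               evaluate_delta(ref, 4000, warn_extrapolation = FALSE),
               tolerance = 1e-12)
})
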