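#' Scenario configuration for the synthetic generators
#'
#' Defines the simulated study conditions: a high-plateau drive of about
#' two hours whose altitude follows a piecewise-linear template rising
#' from 3540 m to a 4768 m pass, falling to 4476 m and climbing again to
#' 4663 m; an S-shaped (logistic) fatigue trajectory in the R-R variation
#' coefficient; heart rate coupled to altitude with a steeper response
#' above a 4500 m knee; and blink rates that rise linearly with fatigue.
#' All values are configurable; the defaults are the generator's study
#' conditions.
#'
#' @param duration Drive duration in s (default 7000).
#' @param trim Excitement-period trim in s applied at each end before the
#'   analysis span (default 1000).
#' @param window_length HRV aggregation window in s (default 120).
#' @param altitude_knots_t,altitude_knots_h Altitude template knots
#'   (times s, altitudes m).
#' @param base_hr Seated heart rate at the base altitude, bpm (default 75).
#' @param hr_per_km,hr_per_km_above_knee Altitude-heart rate coupling in
#'   bpm per 1000 m below/above the knee (defaults 5 and 15).
#' @param hr_knee Altitude knee in m (default 4500).
#' @param rrvc_static,rrvc_initial,rrvc_plateau RRVC at seated rest, at
#'   the start of the analysis span, and at the fatigue plateau
#'   (defaults 0.03, 0.05, 0.12).
#' @param fatigue_midpoint,fatigue_scale Logistic midpoint (s) and time
#'   scale (s) of the fatigue trajectory (defaults 3000 and 600).
#' @param bf_static,bf_initial Blink-frequency baselines, times/min
#'   (defaults 10 and 15).
#' @param dfd_noise Multiplicative noise SD applied to the window-level
#'   blink fatigue values (default 0.05).
#' @param rr_bounds Physiological truncation bounds for generated R-R
#'   intervals, ms (default c(300, 2000)).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(duration = 7000, trim = 1000,
                            window_length = 120,
                            altitude_knots_t = c(0, 3000, 5000, 7000),
                            altitude_knots_h = c(3540, 4768, 4476, 4663),
                            base_hr = 75, hr_per_km = 5,
                            hr_per_km_above_knee = 15, hr_knee = 4500,
                            rrvc_static = 0.03, rrvc_initial = 0.05,
                            rrvc_plateau = 0.12,
                            fatigue_midpoint = 3000, fatigue_scale = 600,
                            bf_static = 10, bf_initial = 15,
                            dfd_noise = 0.05, rr_bounds = c(300, 2000)) {
  cfg <- as.list(environment())
  if (duration <= 2 * trim + window_length)
    stop("duration too short for the requested trim and window")
  if (rrvc_plateau <= 0 || rrvc_plateau >= 1 ||
      rrvc_initial <= 0 || rrvc_static <= 0)
    stop("RRVC trajectory parameters must lie in (0, 1)")
  if (base_hr <= 0 || bf_static < 0 || bf_initial < 0)
    stop("all rates must be positive")
  class(cfg) <- "scenario_config"
  cfg
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Generate a piecewise-linear altitude profile
#'
#' @param knots_t Knot times in s, strictly increasing.
#' @param knots_h Knot altitudes in m.
#' @param dt Sampling interval in s (default 10).
#' @return An [altitude_profile()].
#' @examples
#' gen_altitude_profile(c(0, 3600), c(3540, 4768))
#' @export
gen_altitude_profile <- function(knots_t, knots_h, dt = 10) {
  if (length(knots_t) != length(knots_h)) stop("knot vectors differ in length")
  if (length(knots_t) > 1L && any(diff(knots_t) <= 0))
    stop("knot times must be strictly increasing")
  if (length(knots_t) == 1L)
    return(altitude_profile(knots_t, knots_h))
  tt <- seq(knots_t[1], knots_t[length(knots_t)], by = dt)
  if (tt[length(tt)] < knots_t[length(knots_t)])
    tt <- c(tt, knots_t[length(knots_t)])
  altitude_profile(tt, stats::approx(knots_t, knots_h, xout = tt)$y)
}

## planted trajectory functions for a scenario
scenario_trajectories <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  c0 <- config
  t_start <- c0$trim
  L <- function(t) stats::plogis((t - c0$fatigue_midpoint) / c0$fatigue_scale)
  L0 <- L(t_start)
  rrvc <- function(t) {
    c0$rrvc_initial +
      (c0$rrvc_plateau - c0$rrvc_initial) * (L(t) - L0) / (1 - L0)
  }
  profile <- gen_altitude_profile(c0$altitude_knots_t, c0$altitude_knots_h)
  hr <- function(t) {
    h <- altitude_at(profile, t)
    extra <- pmax(h - c0$hr_knee, 0)
    below <- pmin(h, c0$hr_knee) - c0$altitude_knots_h[1]
    c0$base_hr + c0$hr_per_km * below / 1000 +
      c0$hr_per_km_above_knee * extra / 1000
  }
  M <- function(t) 60000 / hr(t)
  bdf <- c0$rrvc_initial - c0$rrvc_static
  dfd <- function(t) (rrvc(t) - c0$rrvc_initial) / bdf
  list(profile = profile, rrvc = rrvc, M = M,
       sdnn = function(t) rrvc(t) * M(t), dfd = dfd, bdf = bdf)
}

#' Generate an R-R interval series with planted fatigue dynamics
#'
#' Beat-by-beat simulation: each interval is drawn from a Normal
#' distribution with time-varying mean M(t) (set by the base heart rate
#' plus the altitude coupling) and standard deviation SDNN(t) (set so that
#' the instantaneous variation coefficient SDNN/M follows the planted
#' S-shaped fatigue trajectory), truncated to the physiological bounds.
#' The planted per-window truth is returned alongside the series so
#' estimators can be validated against it.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return List: `rr` (an [rri_series()] spanning the full drive),
#'   `truth` (data frame `t_mid, M, SDNN, RRVC, DFD` on the post-trim
#'   window grid), `trajectories` (the planted trajectory functions),
#'   `config`.
#' @export
gen_rr_series <- function(config = scenario_config(), seed = 1) {
  traj <- scenario_trajectories(config)
  probe <- seq(0, config$duration, by = 60)
  rr_probe <- traj$rrvc(probe)
  if (any(rr_probe <= 0) || any(rr_probe >= 1))
    stop("trajectory implies RRVC outside (0, 1)")
  rr <- with_seed(seed, {
    times <- numeric(ceiling(config$duration / 0.3) + 2L)
    ivs <- numeric(length(times))
    t <- 0; k <- 0L
    lo <- config$rr_bounds[1]; hi <- config$rr_bounds[2]
    while (t < config$duration) {
      m <- traj$M(t); s <- traj$sdnn(t)
      iv <- stats::rnorm(1, m, s)
      while (iv < lo || iv > hi) iv <- stats::rnorm(1, m, s)
      t <- t + iv / 1000
      k <- k + 1L
      times[k] <- t; ivs[k] <- iv
    }
    rri_series(times[seq_len(k)], ivs[seq_len(k)])
  })
  grid <- window_grid(config)
  truth <- data.frame(
    t_mid = grid$t_mid,
    M = traj$M(grid$t_mid),
    SDNN = traj$sdnn(grid$t_mid),
    RRVC = traj$rrvc(grid$t_mid),
    DFD = traj$dfd(grid$t_mid))
  list(rr = rr, truth = truth, trajectories = traj, config = config)
}

## the post-trim window grid of a scenario
window_grid <- function(config) {
  start <- config$trim
  end <- config$duration - config$trim
  n <- floor((end - start) / config$window_length)
  s <- start + (seq_len(n) - 1L) * config$window_length
  list(start = s, end = s + config$window_length,
       t_mid = s + config$window_length / 2)
}

#' Generate a synthetic ECG trace from an R-R series
#'
#' Places one dominant R deflection (a Gaussian template pulse of ~60 ms
#' total width, matching a narrow QRS complex) at every planted beat
#' time, with optional sinusoidal baseline wander and additive Gaussian
#' noise at a given signal-to-noise ratio.  The planted beat times are
#' attached as an attribute for ground-truth evaluation of peak
#' detectors.
#'
#' @param rr An [rri_series()].
#' @param sampling_rate Sampling rate in Hz (>= 100).
#' @param amplitude R-wave amplitude in mV (default 1).
#' @param pulse_width_s Gaussian sigma of the R deflection in s
#'   (default 0.01).
#' @param snr_db Signal-to-noise ratio in dB; `NULL` (default) adds no
#'   noise.
#' @param baseline_wander Amplitude in mV of a 0.3 Hz baseline drift
#'   (default 0).
#' @param seed Seed for the noise draw.
#' @return An [ecg_trace()] with attribute `beat_times`.
#' @export
gen_ecg <- function(rr, sampling_rate = 250, amplitude = 1,
                    pulse_width_s = 0.01, snr_db = NULL,
                    baseline_wander = 0, seed = 1) {
  stopifnot(inherits(rr, "rri_series"))
  if (sampling_rate < 100) stop("sampling rate must be at least 100 Hz")
  ## include the beat that opens the first interval
  beats <- c(rr$beat_times[1] - rr$intervals[1] / 1000, rr$beat_times)
  t0 <- beats[1] - 0.5
  t_end <- beats[length(beats)] + 0.5
  n <- ceiling((t_end - t0) * sampling_rate) + 1L
  tt <- t0 + (seq_len(n) - 1L) / sampling_rate
  x <- numeric(n)
  half <- ceiling(5 * pulse_width_s * sampling_rate)
  for (b in beats) {
    i0 <- floor((b - t0) * sampling_rate) + 1L
    lo <- max(1L, i0 - half); hi <- min(n, i0 + half)
    idx <- lo:hi
    x[idx] <- x[idx] + amplitude * exp(-((tt[idx] - b)^2) /
                                         (2 * pulse_width_s^2))
  }
  if (baseline_wander > 0)
    x <- x + baseline_wander * sin(2 * pi * 0.3 * tt)
  if (!is.null(snr_db)) {
    p_sig <- mean(x^2)
    sd_noise <- sqrt(p_sig * 10^(-snr_db / 10))
    x <- x + with_seed(seed, stats::rnorm(n, 0, sd_noise))
  }
  out <- ecg_trace(x, sampling_rate, start_time = t0)
  attr(out, "beat_times") <- beats
  out
}

#' Generate blink events from a rate trajectory
#'
#' Simulates spontaneous blinks as an inhomogeneous Poisson process by
#' thinning: candidate events are drawn at the trajectory's maximum rate
#' and retained with probability rate(t)/rate_max.
#'
#' @param rate Blink rate trajectory in times/min: a function of time
#'   (s), or a data frame with columns `t` and `rate` interpolated
#'   linearly.
#' @param duration Span to simulate, s (events on \[0, duration)).
#' @param seed Integer seed.
#' @return A [blink_series()].
#' @examples
#' gen_blinks(function(t) rep(10, length(t)), duration = 600, seed = 7)
#' @export
gen_blinks <- function(rate, duration, seed = 1) {
  if (is.data.frame(rate)) {
    stopifnot(all(c("t", "rate") %in% names(rate)))
    rate_fun <- stats::approxfun(rate$t, rate$rate, rule = 2)
  } else if (is.function(rate)) {
    rate_fun <- rate
  } else stop("rate must be a function or a (t, rate) data frame")
  probe <- seq(0, duration, length.out = 1024L)
  r <- rate_fun(probe)
  if (any(!is.finite(r)) || any(r < 0))
    stop("blink rate trajectory must be nonnegative")
  rmax <- max(r)
  if (rmax == 0) return(blink_series(numeric(0)))
  lambda_s <- rmax / 60  # events per second
  with_seed(seed, {
    n_cand <- stats::rpois(1, lambda_s * duration)
    if (n_cand == 0) return(blink_series(numeric(0)))
    cand <- sort(stats::runif(n_cand, 0, duration))
    keep <- stats::runif(n_cand) < rate_fun(cand) / rmax
    blink_series(cand[keep])
  })
}

#' Generate a fully coupled scenario with known correction factor
#'
#' Constructs a dataset in which the true altitude correction factor is
#' exactly `delta_star`: the blink-based fatigue trajectory is set to
#' delta_star(h(t)) times the HRV-based fatigue trajectory (optionally
#' perturbed by multiplicative noise), and the blink rates are back-solved
#' through the blink fatigue definition so that running the full pipeline
#' on the generated recordings should recover `delta_star`.  Used for
#' end-to-end parameter-recovery validation.
#'
#' @param config A [scenario_config()]; `config$dfd_noise` sets the
#'   multiplicative noise SD on the window-level blink fatigue values
#'   (0 gives the exact noiseless construction).
#' @param delta_star The true correction factor: a `delta_model`, a
#'   function of altitude (m), or a numeric vector of ascending-power
#'   polynomial coefficients.
#' @param seed Integer seed.
#' @param beat_level Also generate the beat-level R-R series and blink
#'   events (default TRUE); window-level truth is always returned.
#' @return List: `hrv_dfd` and `blink_dfd` ([dfd_series()] on the
#'   post-trim window grid), `altitude` profile, `h_at_windows`,
#'   `delta_star_at_windows`, `baselines` (planted
#'   [compute_baselines()]-compatible object), `truth`, `config`, and
#'   when `beat_level` is TRUE also `rr` and `blinks`.
#' @export
gen_coupled_scenario <- function(config = scenario_config(),
                                 delta_star = delta_reference("up"),
                                 seed = 1, beat_level = TRUE) {
  delta_fun <-
    if (inherits(delta_star, "delta_model"))
      function(h) evaluate_delta(delta_star, h, warn_extrapolation = FALSE)
    else if (is.function(delta_star)) delta_star
    else if (is.numeric(delta_star)) function(h) eval_poly(delta_star, h)
    else stop("delta_star must be a delta_model, function, or coefficients")

  traj <- scenario_trajectories(config)
  grid <- window_grid(config)
  h_w <- altitude_at(traj$profile, grid$t_mid)
  d_star <- delta_fun(h_w)
  if (any(!is.finite(d_star)) || any(d_star <= 0))
    stop("delta_star must be positive over the profile's altitude range")

  hrv_true <- traj$dfd(grid$t_mid)
  noise <- if (config$dfd_noise > 0)
    with_seed(seed, stats::rnorm(length(grid$t_mid), 0, config$dfd_noise))
  else rep(0, length(grid$t_mid))
  blink_vals <- d_star * hrv_true * (1 + noise)

  bdf_blink <- config$bf_initial - config$bf_static
  bf_w <- config$bf_initial + blink_vals * bdf_blink
  if (any(bf_w < 0))
    stop("infeasible coupling: back-solved blink rate is negative")

  baselines <- structure(
    list(rrvc_static = config$rrvc_static,
         rrvc_initial = config$rrvc_initial,
         bdf = traj$bdf,
         bf_static = config$bf_static, bf_initial = config$bf_initial,
         bdf_blink = bdf_blink),
    class = "fatigue_baselines")

  out <- list(
    hrv_dfd = dfd_series(grid$t_mid, hrv_true, "hrv",
                         config$window_length),
    blink_dfd = dfd_series(grid$t_mid, blink_vals, "blink",
                           config$window_length),
    altitude = traj$profile,
    h_at_windows = h_w,
    delta_star_at_windows = d_star,
    baselines = baselines,
    truth = list(dfd = traj$dfd, rrvc = traj$rrvc, delta = delta_fun,
                 window_grid = grid),
    config = config)

  if (beat_level) {
    gen <- gen_rr_series(config, seed = seed)
    out$rr <- gen$rr
    ## blink rate trajectory interpolating the window-level rates,
    ## anchored at the initial rate outside the analysis span
    rate_df <- data.frame(
      t = c(0, grid$t_mid, config$duration),
      rate = c(bf_w[1], bf_w, bf_w[length(bf_w)]))
    out$blinks <- gen_blinks(rate_df, config$duration, seed = seed + 1L)
  }
  out
}
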