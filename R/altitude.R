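#' Classify slope segments of an altitude profile
#'
#' Altitude affects heart rate oppositely on climbs and descents, so the
#' correction factor is calibrated per slope direction.  The altitude
#' gradient is smoothed by a moving average and each time point labeled
#' `up`, `down` or `flat` by comparing the smoothed gradient against the
#' flat threshold; contiguous runs become segments, and runs shorter than
#' `min_duration` are merged into their longer neighbour so that brief
#' undulations do not fragment the segmentation.
#'
#' @param profile An [altitude_profile()].
#' @param flat_threshold Absolute smoothed gradient below which a point is
#'   flat, in m/min (default 0.25, i.e. 0.5 m per 2-min window).
#' @param smoothing_window Gradient smoothing window in s (default 60).
#' @param min_duration Minimum segment duration in s (default 300).
#' @return Data frame of class `slope_segments` with columns
#'   `start, end, slope_class, mean_gradient` (gradient in m/s); the
#'   segments partition the profile span.
#' @export
classify_slope <- function(profile, flat_threshold = 0.25,
                           smoothing_window = 60, min_duration = 300) {
  stopifnot(inherits(profile, "altitude_profile"))
  t <- profile$times; h <- profile$altitudes
  if (length(t) < 2L) {
    seg <- data.frame(start = t[1], end = t[1], slope_class = "flat",
                      mean_gradient = 0, stringsAsFactors = FALSE)
    class(seg) <- c("slope_segments", "data.frame")
    return(seg)
  }
  ## central-difference gradient (m/s)
  n <- length(t)
  g <- numeric(n)
  g[1] <- (h[2] - h[1]) / (t[2] - t[1])
  g[n] <- (h[n] - h[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L)
    g[2:(n - 1)] <- (h[3:n] - h[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  ## moving-average smoothing over smoothing_window seconds
  dt <- stats::median(diff(t))
  k <- max(1L, round(smoothing_window / dt))
  if (k > 1L) {
    if (k %% 2L == 0L) k <- k + 1L
    gs <- stats::filter(g, rep(1 / k, k), sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
    g <- as.numeric(gs)
  }
  thr <- flat_threshold / 60  # m/min -> m/s
  cls <- ifelse(g > thr, "up", ifelse(g < -thr, "down", "flat"))

  seg_table <- function(cls) {
    r <- rle(cls)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    data.frame(start = t[idx_start],
               end = t[idx_end],
               i_start = idx_start, i_end = idx_end,
               slope_class = r$values, stringsAsFactors = FALSE)
  }
  seg <- seg_table(cls)
  ## merge short runs into their longer neighbour until stable
  repeat {
    dur <- seg$end - seg$start
    short <- which(dur < min_duration)
    if (length(short) == 0L || nrow(seg) == 1L) break
    j <- short[which.min(dur[short])]
    nb <- if (j == 1L) 2L
          else if (j == nrow(seg)) j - 1L
          else if (dur[j - 1L] >= dur[j + 1L]) j - 1L else j + 1L
    cls[seg$i_start[j]:seg$i_end[j]] <- seg$slope_class[nb]
    seg <- seg_table(cls)
  }
  ## segment boundaries meet halfway between adjacent profile points
  out <- data.frame(start = seg$start, end = seg$end,
                    slope_class = seg$slope_class, stringsAsFactors = FALSE)
  if (nrow(out) > 1L) {
    mid <- (seg$end[-nrow(seg)] + seg$start[-1L]) / 2
    out$end[-nrow(out)] <- mid
    out$start[-1L] <- mid
  }
  out$start[1L] <- t[1]; out$end[nrow(out)] <- t[n]
  out$mean_gradient <- vapply(seq_len(nrow(seg)), function(j)
    mean(g[seg$i_start[j]:seg$i_end[j]]), numeric(1))
  class(out) <- c("slope_segments", "data.frame")
  out
}

#' Slope class at given times
#'
#' @param segments A [classify_slope()] result.
#' @param t Times (s).
#' @return Character vector of classes (`up`/`down`/`flat`); times outside
#'   the segmentation get `NA`.
#' @export
slope_class_at <- function(segments, t) {
  stopifnot(inherits(segments, "slope_segments"))
  out <- rep(NA_character_, length(t))
  for (j in seq_len(nrow(segments))) {
    inside <- t >= segments$start[j] &
      (t < segments$end[j] | (j == nrow(segments) & t <= segments$end[j]))
    out[inside] <- segments$slope_class[j]
  }
  out
}

#' Pointwise correction-factor estimates
#'
#' The correction relation rDFD = delta(h) * DFD, together with the
#' requirement that the revised series track the blink reference, gives a
#' pointwise estimate delta_i = blink-DFD_i / hrv-DFD_i at the altitude of
#' window i.  Windows where the HRV fatigue degree is near its zero
#' crossing (|hrv-DFD_i| <= epsilon) are excluded to avoid ratio blow-up;
#' the exclusion count is reported.
#'
#' @param blink,hrv [dfd_series()] objects on the same window grid (the
#'   pairing is an inner join on window mid-time).
#' @param altitude_at_windows Altitudes (m) at the *hrv* series' window
#'   mid-times, or an [altitude_profile()] to interpolate.
#' @param epsilon Zero-crossing guard on |hrv-DFD| (default 0.05).
#' @return Data frame of class `delta_pairs` with columns `t, h, delta`
#'   and attribute `n_excluded`.
#' @export
pointwise_delta <- function(blink, hrv, altitude_at_windows,
                            epsilon = 0.05) {
  stopifnot(inherits(blink, "dfd_series"), inherits(hrv, "dfd_series"))
  if (inherits(altitude_at_windows, "altitude_profile"))
    altitude_at_windows <- altitude_at(altitude_at_windows, hrv$t)
  if (length(altitude_at_windows) != length(hrv$t))
    stop("altitude_at_windows must match the hrv window grid")
  j <- match(round(hrv$t, 6), round(blink$t, 6))
  common <- which(!is.na(j))
  if (length(common) == 0L) stop("series share no windows")
  hv <- hrv$values[common]
  bv <- blink$values[j[common]]
  hh <- altitude_at_windows[common]
  tt <- hrv$t[common]
  use <- abs(hv) > epsilon
  if (sum(use) < 5L)
    stop("insufficient calibration support: fewer than 5 usable pairs")
  out <- data.frame(t = tt[use], h = hh[use], delta = bv[use] / hv[use])
  attr(out, "n_excluded") <- sum(!use)
  class(out) <- c("delta_pairs", "data.frame")
  out
}

#' Calibrate the altitude correction factor
#'
#' Fits a least-squares cubic in altitude to pointwise correction-factor
#' estimates from one slope class, delta(h) = c0 + c1 h + c2 h^2 + c3 h^3.
#' The altitude axis is centered and scaled internally for conditioning
#' and the coefficients mapped back to the original metre scale.  Because
#' each pointwise estimate is a ratio of two fatigue values, its error is
#' multiplicative (proportional to its magnitude); the default
#' `"relative"` weighting therefore minimizes relative rather than
#' absolute residuals, which stabilizes the fit where delta is small.
#'
#' @param pairs A [pointwise_delta()] result or data frame with columns
#'   `h`, `delta`; at least 5 pairs spanning at least `min_span` metres.
#' @param slope_class `"up"`, `"down"` or `"flat"`.
#' @param degree Polynomial degree (default 3).
#' @param min_span Minimum altitude span in m (default 200).
#' @param weighting `"relative"` (one-step reweighted least squares with
#'   weights 1/fitted^2, the multiplicative error model) or `"none"`
#'   (ordinary least squares).
#' @return Object of class `delta_model`: `slope_class`, `coef` (c0..c3),
#'   `h_range`, `rss`, `F`, `sig_F`, `n`.
#' @export
calibrate_delta <- function(pairs, slope_class = c("up", "down", "flat"),
                            degree = 3L, min_span = 200,
                            weighting = c("relative", "none")) {
  slope_class <- match.arg(slope_class)
  weighting <- match.arg(weighting)
  stopifnot(all(c("h", "delta") %in% names(pairs)))
  h <- pairs$h; d <- pairs$delta
  if (length(h) < max(5L, degree + 2L))
    stop("insufficient calibration support: fewer than 5 usable pairs")
  if (diff(range(h)) < min_span)
    stop("altitude span too narrow for a stable cubic (",
         round(diff(range(h))), " m < ", min_span, " m)")
  w <- NULL
  if (weighting == "relative") {
    ## one-step reweighting: variance grows with the true factor, so use
    ## the fitted values of an initial unweighted fit, floored to avoid
    ## weight blow-up where the fitted factor crosses zero
    pilot <- cubic_ls(h, d, degree = degree)
    floor_d <- pmax(0.05 * stats::median(abs(d)), 1e-8)
    w <- 1 / pmax(abs(pilot$fitted), floor_d)^2
  }
  ls <- cubic_ls(h, d, degree = degree, weights = w)
  structure(
    list(slope_class = slope_class, coef = ls$coef, h_range = range(h),
         rss = ls$rss, F = ls$F, sig_F = ls$sig_F, n = length(h)),
    class = "delta_model")
}

#' @export
print.delta_model <- function(x, ...) {
  cat(sprintf("<delta_model %s> delta(h) = %s over [%.0f, %.0f] m\n",
              x$slope_class, format_poly(x$coef, "h"),
              x$h_range[1], x$h_range[2]))
  invisible(x)
}

format_poly <- function(coef, var) {
  terms <- vapply(seq_along(coef), function(j) {
    p <- j - 1L
    if (p == 0) sprintf("%.6g", coef[j])
    else sprintf("%+.6g %s^%d", coef[j], var, p)
  }, character(1))
  paste(terms, collapse = " ")
}

#' Evaluate a correction-factor model
#'
#' Polynomial evaluation (Horner scheme) of delta(h).  A warning is
#' issued when `h` falls outside the model's calibration altitude range,
#' where the cubic extrapolates without support.
#'
#' @param model A [calibrate_delta()] result or [delta_reference()] model.
#' @param h Altitudes in m.
#' @param warn_extrapolation Emit the extrapolation warning (default TRUE).
#' @return delta values (dimensionless).
#' @examples
#' evaluate_delta(delta_reference("up"), 4000)    # 4.375
#' @export
evaluate_delta <- function(model, h, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "delta_model"))
  if (any(!is.finite(h))) stop("altitudes must be finite")
  if (warn_extrapolation && !is.null(model$h_range) &&
      any(h < model$h_range[1] | h > model$h_range[2]))
    warning("evaluating delta(h) outside its calibration altitude range")
  eval_poly(model$coef, h)
}

## Horner evaluation, ascending-power coefficients
eval_poly <- function(coef, x) {
  y <- rep(coef[length(coef)], length(x))
  for (j in rev(seq_len(length(coef) - 1L)))
    y <- y * x + coef[j]
  y
}

#' Published correction-factor models
#'
#' The calibrated cubic correction factors for the 3540-4768 m study
#' range, one per slope direction:
#' upslope delta_u(h) = 366.711 - 0.302 h + 8.169e-5 h^2 - 7.209e-9 h^3,
#' downslope delta_d(h) = 493.703 - 0.348 h + 8.219e-5 h^2 - 6.473e-9 h^3.
#' Shipped for evaluation and comparison; new data should be calibrated
#' with [calibrate_delta()].
#'
#' @param slope_class `"up"` or `"down"`.
#' @return A `delta_model`.
#' @export
delta_reference <- function(slope_class = c("up", "down")) {
  slope_class <- match.arg(slope_class)
  coef <- if (slope_class == "up")
    c(366.711, -0.302, 8.169e-5, -7.209e-9)
  else
    c(493.703, -0.348, 8.219e-5, -6.473e-9)
  structure(
    list(slope_class = slope_class, coef = coef, h_range = c(3540, 4768),
         rss = NA_real_, F = NA_real_, sig_F = NA_real_, n = NA_integer_),
    class = "delta_model")
}

#' Published revised-fatigue trend models
#'
#' Reference cubics describing the revised fatigue degree as a function
#' of driving time t (s) on the study's upslope and downslope segments:
#' upslope  rDFD_u(t) = 8.658 + 0.008 t - 3.173e-6 t^2 + 5.850e-10 t^3,
#' downslope rDFD_d(t) = 4.436 + 0.004 t - 2.173e-6 t^2 + 5.348e-10 t^3.
#' Shipped for evaluation only; they summarize the original field data
#' and are not recomputable from other inputs.
#'
#' @param slope_class `"up"` or `"down"`.
#' @return A `trend_model` (span 0-7200 s).
#' @export
rdfd_reference <- function(slope_class = c("up", "down")) {
  slope_class <- match.arg(slope_class)
  coef <- if (slope_class == "up")
    c(8.658, 0.008, -3.173e-6, 5.850e-10)
  else
    c(4.436, 0.004, -2.173e-6, 5.348e-10)
  out <- structure(
    list(coef = coef, rss = NA_real_, F = NA_real_, sig_F = NA_real_,
         df = c(NA_real_, NA_real_), span = c(0, 7200), n = NA_integer_,
         sigma = NA_real_),
    class = "trend_model")
  out$inflection_time <- detect_breakpoints(out)
  out
}

#' Evaluate a trend model
#'
#' @param object A `trend_model`.
#' @param t Times (s).
#' @param ... Unused.
#' @return Fitted polynomial values at `t`.
#' @export
predict.trend_model <- function(object, t, ...) {
  eval_poly(object$coef, t)
}

#' Revise the HRV fatigue degree for altitude
#'
#' Applies the altitude correction rDFD_i = delta(h_i) * DFD_i window by
#' window.  Either a single `delta_model` is used throughout, or a named
#' list of models (`up`, `down`, optionally `flat`) is combined with a
#' slope segmentation so each window uses the model of its slope class.
#' Flat windows default to delta = 1 (no correction) when no flat model
#' is supplied, reflecting the absence of altitude dependence on
#' low-variation segments.
#'
#' @param hrv A [dfd_series()] with `source = "hrv"`.
#' @param model A `delta_model` or named list of them.
#' @param altitude_at_windows Altitudes (m) at the window mid-times, or an
#'   [altitude_profile()].
#' @param segments Optional [classify_slope()] result (required when
#'   `model` is a list).
#' @param warn_extrapolation Passed to [evaluate_delta()].
#' @return A [dfd_series()] with `source = "revised"`.
#' @export
revise_dfd <- function(hrv, model, altitude_at_windows, segments = NULL,
                       warn_extrapolation = FALSE) {
  stopifnot(inherits(hrv, "dfd_series"))
  if (inherits(altitude_at_windows, "altitude_profile"))
    altitude_at_windows <- altitude_at(altitude_at_windows, hrv$t)
  if (length(altitude_at_windows) != length(hrv$t))
    stop("altitude_at_windows must match the window grid")
  if (inherits(model, "delta_model")) {
    delta <- evaluate_delta(model, altitude_at_windows,
                            warn_extrapolation = warn_extrapolation)
  } else {
    if (is.null(segments))
      stop("a slope segmentation is required with a per-class model list")
    cls <- slope_class_at(segments, hrv$t)
    if (any(is.na(cls)))
      stop("windows fall outside the slope segmentation")
    delta <- numeric(length(hrv$t))
    for (cl in unique(cls)) {
      sel <- cls == cl
      if (!is.null(model[[cl]])) {
        delta[sel] <- evaluate_delta(model[[cl]], altitude_at_windows[sel],
                                     warn_extrapolation = warn_extrapolation)
      } else if (cl == "flat") {
        delta[sel] <- 1
      } else {
        stop("no correction model for slope class '", cl, "'")
      }
    }
  }
  dfd_series(hrv$t, delta * hrv$values, source = "revised",
             window_length = hrv$window_length)
}

#' Agreement between two fatigue curves
#'
#' Quantifies how closely two fatigue series agree on their common window
#' grid: the sum of squared differences, and the regression F statistic,
#' its significance, and the coefficient of determination R^2 from a
#' simple linear regression of `b` on `a` (the F test of no linear
#' relationship between the curves).
#'
#' @param a,b [dfd_series()] objects with at least 3 common windows.
#' @return Object of class `curve_agreement`: `ss`, `F`, `sig_F`, `r2`,
#'   `n`, `labels`.
#' @export
curve_agreement <- function(a, b) {
  stopifnot(inherits(a, "dfd_series"), inherits(b, "dfd_series"))
  j <- match(round(a$t, 6), round(b$t, 6))
  common <- which(!is.na(j))
  if (length(common) < 3L) stop("fewer than 3 common windows")
  av <- a$values[common]; bv <- b$values[j[common]]
  ss <- sum((av - bv)^2)
  if (stats::sd(av) == 0) {
    Fv <- NA_real_; sig <- NA_real_; r2 <- NA_real_
  } else {
    fit <- stats::lm(bv ~ av)
    sm <- quiet_summary(fit)
    r2 <- sm$r.squared
    fs <- sm$fstatistic
    if (is.null(fs)) { Fv <- NA_real_; sig <- NA_real_ }
    else {
      Fv <- unname(fs[1])
      sig <- unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    }
  }
  structure(list(ss = ss, F = Fv, sig_F = sig, r2 = r2,
                 n = length(common),
                 labels = c(a$source, b$source)),
            class = "curve_agreement")
}

#' @export
print.curve_agreement <- function(x, ...) {
  cat(sprintf(
    "<curve_agreement %s vs %s> SS = %.4g, F = %.4g, sig F = %.4g, R2 = %.4g (n = %d)\n",
    x$labels[1], x$labels[2], x$ss, x$F, x$sig_F, x$r2, x$n))
  invisible(x)
}

#' Altitude-independence check on a flat segment
#'
#' On segments with little altitude change the correction factor should
#' not depend on altitude; the check regresses the pointwise delta
#' estimates on altitude and reports the regression F statistic and its
#' significance.  The method's validity criterion is *non-rejection*:
#' significance F >= `alpha` means no altitude dependence is detectable
#' and delta = 1 is adequate there.
#'
#' @param pairs A [pointwise_delta()] result (>= 5 pairs) from a flat or
#'   low-variation segment.
#' @param alpha Rejection threshold (default 0.05).
#' @return List of class `flat_check`: `slope`, `F`, `sig_F`, `n`,
#'   `altitude_independent` (logical).
#' @export
flat_segment_check <- function(pairs, alpha = 0.05) {
  stopifnot(all(c("h", "delta") %in% names(pairs)))
  h <- pairs$h; d <- pairs$delta
  if (length(h) < 5L) stop("at least 5 pairs are required")
  if (stats::sd(h) == 0) stop("degenerate input: all pairs at one altitude")
  if (stats::sd(d) == 0) {
    out <- list(slope = 0, F = 0, sig_F = 1, n = length(h),
                altitude_independent = TRUE)
  } else {
    fit <- stats::lm(d ~ h)
    sm <- quiet_summary(fit)
    fs <- sm$fstatistic
    Fv <- unname(fs[1])
    sig <- unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    out <- list(slope = unname(stats::coef(fit)[2]), F = Fv, sig_F = sig,
                n = length(h), altitude_independent = sig >= alpha)
  }
  class(out) <- "flat_check"
  out
}

#' @export
print.flat_check <- function(x, ...) {
  cat(sprintf(
    "<flat_check> slope %.3g per m, F = %.4g, sig F = %.4g (n = %d): %s\n",
    x$slope, x$F, x$sig_F, x$n,
    if (x$altitude_independent) "no altitude dependence detected"
    else "altitude dependence detected"))
  invisible(x)
}

#' Correction-model JSON round trip
#'
#' Writes and reads a `delta_model` as JSON (full double precision), the
#' exchange format used by the command-line tools.
#'
#' @param model A `delta_model`.
#' @param path JSON file path.
#' @return `read_delta_model` returns the `delta_model`;
#'   `write_delta_model` returns `path` invisibly.
#' @export
write_delta_model <- function(model, path) {
  stopifnot(inherits(model, "delta_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_delta_model
#' @export
read_delta_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coef <- as.numeric(x$coef)
  x$h_range <- as.numeric(x$h_range)
  structure(x, class = "delta_model")
}
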