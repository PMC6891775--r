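#' Aggregate an R-R series into HRV windows
#'
#' Partitions the series into consecutive non-overlapping \[start, end)
#' windows of `window_length` seconds and computes the time-domain HRV
#' statistics per window: M (mean R-R interval, ms), SDNN (sample standard
#' deviation of the R-R intervals, ms) and their ratio RRVC = SDNN / M, the
#' variation coefficient of the R-R intervals.  An interval belongs to the
#' window containing the time of its closing beat, so each interval is
#' counted exactly once.  Windows with fewer than `min_beats` intervals are
#' kept in the table but flagged unusable and excluded from downstream
#' fits.
#'
#' @param rr An [rri_series()].
#' @param window_length Window length in s (default 120, i.e. the 2-min
#'   aggregation interval).
#' @param min_beats Minimum interval count for a usable window (default 10).
#' @param origin Start time of the first window; defaults to the first
#'   beat time of `rr`.
#' @return A data frame of class `hrv_windows` with columns
#'   `i, start, end, t_mid, n_beats, M, SDNN, RRVC, usable` and attribute
#'   `window_length`.
#' @examples
#' rr <- rri_series(cumsum(rep(1, 600)), rep(1000, 600))
#' w <- window_hrv(rr, 120)
#' @export
window_hrv <- function(rr, window_length = 120, min_beats = 10,
                       origin = NULL) {
  stopifnot(inherits(rr, "rri_series"))
  if (!is.finite(window_length) || window_length <= 0)
    stop("window_length must be positive")
  if (is.null(origin)) origin <- rr$beat_times[1]
  t_end <- rr$beat_times[length(rr$beat_times)]
  if (t_end - origin < window_length)
    stop("series shorter than one window")
  n_win <- floor((t_end - origin) / window_length)
  if (t_end == origin + n_win * window_length)  # end point falls on boundary
    n_win <- n_win  # [start, end): the boundary beat opens no extra window
  else
    n_win <- n_win + 1L
  idx <- floor((rr$beat_times - origin) / window_length) + 1L
  ok <- idx >= 1L & idx <= n_win
  out <- data.frame(
    i = seq_len(n_win),
    start = origin + (seq_len(n_win) - 1L) * window_length,
    end = origin + seq_len(n_win) * window_length
  )
  out$t_mid <- (out$start + out$end) / 2
  out$n_beats <- as.integer(tabulate(idx[ok], nbins = n_win))
  stats_by <- function(f, default) {
    v <- rep(default, n_win)
    agg <- tapply(rr$intervals[ok], factor(idx[ok], levels = seq_len(n_win)), f)
    v[!is.na(agg)] <- agg[!is.na(agg)]
    v
  }
  out$M <- stats_by(mean, NA_real_)
  out$SDNN <- stats_by(function(x) if (length(x) > 1L) stats::sd(x) else 0,
                       NA_real_)
  out$RRVC <- out$SDNN / out$M
  out$usable <- out$n_beats >= min_beats
  if (!any(out$usable))
    stop("no window reaches the minimum beat count")
  attr(out, "window_length") <- window_length
  class(out) <- c("hrv_windows", "data.frame")
  out
}

#' Variation coefficient of R-R intervals
#'
#' RRVC = SDNN / M: the window's standard deviation of R-R intervals
#' divided by its mean R-R interval.  Dimensionless and invariant under a
#' uniform rescaling of all intervals.
#'
#' @param SDNN Standard deviation of R-R intervals (ms), >= 0.
#' @param M Mean R-R interval (ms), > 0.
#' @return RRVC (dimensionless).
#' @export
compute_rrvc <- function(SDNN, M) {
  if (any(!is.finite(M)) || any(M <= 0))
    stop("mean R-R interval M must be positive")
  if (any(!is.finite(SDNN)) || any(SDNN < 0))
    stop("SDNN must be nonnegative")
  SDNN / M
}

#' Pre-drive fatigue baselines
#'
#' The fatigue statistic is anchored to two baselines: RRVC_static, the
#' variation coefficient measured while the driver sits still before the
#' drive, and RRVC_initial, the RRVC of the first driving window(s) after
#' the excitement-period trim.  Their difference BDF = RRVC_initial -
#' RRVC_static is the pre-existing ("before driving") fatigue and the
#' denominator of the fatigue degree, so it must be bounded away from
#' zero.  Blink-frequency analogues (times/min) may be supplied for the
#' blink-based statistic.
#'
#' @param initial_windows An `hrv_windows` table for the (trimmed) drive;
#'   the first `k` usable windows define RRVC_initial.
#' @param static_rr An [rri_series()] recorded at seated rest; its whole
#'   span is aggregated into a single RRVC.  Alternatively pass
#'   `rrvc_static` directly.
#' @param k Number of leading usable windows averaged into RRVC_initial
#'   (default 1).
#' @param rrvc_static Scalar override when no static recording exists.
#' @param bf_static,bf_initial Optional blink-frequency baselines
#'   (times/min).
#' @param epsilon Degeneracy guard: error if
#'   `|RRVC_initial - RRVC_static| <= epsilon` (default 1e-6).
#' @return An object of class `fatigue_baselines`: a list with
#'   `rrvc_static`, `rrvc_initial`, `bdf`, and optionally `bf_static`,
#'   `bf_initial`, `bdf_blink`.
#' @export
compute_baselines <- function(initial_windows, static_rr = NULL, k = 1,
                              rrvc_static = NULL, bf_static = NULL,
                              bf_initial = NULL, epsilon = 1e-6) {
  if (is.null(rrvc_static)) {
    if (is.null(static_rr))
      stop("supply either a static R-R recording or rrvc_static")
    stopifnot(inherits(static_rr, "rri_series"))
    iv <- static_rr$intervals
    if (length(iv) < 2L) stop("static recording too short")
    rrvc_static <- stats::sd(iv) / mean(iv)
  }
  stopifnot(inherits(initial_windows, "hrv_windows"))
  use <- initial_windows[initial_windows$usable, , drop = FALSE]
  if (nrow(use) < k) stop("fewer usable windows than k")
  rrvc_initial <- mean(use$RRVC[seq_len(k)])
  bdf <- rrvc_initial - rrvc_static
  if (abs(bdf) <= epsilon)
    stop("degenerate baseline: |RRVC_initial - RRVC_static| ~ 0")
  out <- list(rrvc_static = rrvc_static, rrvc_initial = rrvc_initial,
              bdf = bdf)
  if (!is.null(bf_static) && !is.null(bf_initial)) {
    bdf_blink <- bf_initial - bf_static
    if (abs(bdf_blink) <= epsilon)
      stop("degenerate blink baseline: |BF_initial - BF_static| ~ 0")
    out$bf_static <- bf_static
    out$bf_initial <- bf_initial
    out$bdf_blink <- bdf_blink
  }
  class(out) <- "fatigue_baselines"
  out
}

#' @export
print.fatigue_baselines <- function(x, ...) {
  cat(sprintf("<fatigue_baselines> RRVC static %.5f, initial %.5f, BDF %.5f\n",
              x$rrvc_static, x$rrvc_initial, x$bdf))
  if (!is.null(x$bdf_blink))
    cat(sprintf("  blink: static %.2f, initial %.2f /min, BDF %.2f\n",
                x$bf_static, x$bf_initial, x$bdf_blink))
  invisible(x)
}

#' Driving fatigue degree from windowed HRV
#'
#' Per window i the cumulative fatigue is FC_i = RRVC_i - RRVC_static, the
#' cumulative *driving* fatigue is DFC_i = RRVC_i - RRVC_initial, and the
#' driving fatigue degree normalizes the latter by the pre-drive fatigue:
#' DFD_i = DFC_i / BDF with BDF = RRVC_initial - RRVC_static.  The algebra
#' implies FC_i - DFC_i = BDF and DFD_i * BDF = DFC_i for every window;
#' both identities hold to machine precision in the returned table.
#'
#' @param windows An `hrv_windows` table (only usable windows enter).
#' @param baselines A [compute_baselines()] result.
#' @return A list of class `fatigue_metrics`: `table` (data frame with
#'   `i, t_mid, RRVC, FC, DFC, DFD`), `bdf`, and `dfd` (a
#'   [dfd_series()] with `source = "hrv"`).
#' @export
compute_fatigue_metrics <- function(windows, baselines) {
  stopifnot(inherits(windows, "hrv_windows"),
            inherits(baselines, "fatigue_baselines"))
  w <- windows[windows$usable, , drop = FALSE]
  if (nrow(w) == 0L) stop("no usable windows")
  fc <- w$RRVC - baselines$rrvc_static
  dfc <- w$RRVC - baselines$rrvc_initial
  dfd <- dfc / baselines$bdf
  tab <- data.frame(i = w$i, t_mid = w$t_mid, M = w$M, SDNN = w$SDNN,
                    RRVC = w$RRVC, FC = fc, DFC = dfc, DFD = dfd)
  structure(
    list(table = tab, bdf = baselines$bdf,
         dfd = dfd_series(w$t_mid, dfd, source = "hrv",
                          window_length = attr(windows, "window_length"))),
    class = "fatigue_metrics")
}

#' @export
print.fatigue_metrics <- function(x, ...) {
  cat(sprintf("<fatigue_metrics> %d windows, BDF %.5f, DFD range [%.3g, %.3g]\n",
              nrow(x$table), x$bdf, min(x$table$DFD), max(x$table$DFD)))
  invisible(x)
}

#' Average HRV windows across a driver cohort
#'
#' HRV patterns are similar across drivers even though absolute heart
#' rates differ, so the cohort statistic averages the HRV parameters (M
#' and SDNN) across the drivers contributing to each window and recomputes
#' RRVC from the averaged parameters.  Windows are aligned by window
#' ordinal `i`; a driver missing a window simply does not contribute to
#' it.
#'
#' @param per_driver List of `hrv_windows` tables on a common window grid.
#' @return An `hrv_windows` table with an extra `n_drivers` column.
#' @export
cohort_average <- function(per_driver) {
  if (length(per_driver) == 0L) stop("empty cohort")
  lapply(per_driver, function(w) stopifnot(inherits(w, "hrv_windows")))
  if (length(per_driver) == 1L) {
    out <- per_driver[[1L]]
    out$n_drivers <- 1L
    return(out)
  }
  all_w <- do.call(rbind, lapply(per_driver, function(w)
    w[w$usable, c("i", "start", "end", "t_mid", "n_beats", "M", "SDNN")]))
  agg <- do.call(rbind, lapply(split(all_w, all_w$i), function(g) {
    data.frame(i = g$i[1], start = g$start[1], end = g$end[1],
               t_mid = g$t_mid[1], n_beats = as.integer(round(mean(g$n_beats))),
               M = mean(g$M), SDNN = mean(g$SDNN), n_drivers = nrow(g))
  }))
  agg <- agg[order(agg$i), , drop = FALSE]
  agg$RRVC <- agg$SDNN / agg$M
  agg$usable <- TRUE
  rownames(agg) <- NULL
  agg <- agg[, c("i", "start", "end", "t_mid", "n_beats", "M", "SDNN",
                 "RRVC", "usable", "n_drivers")]
  attr(agg, "window_length") <- attr(per_driver[[1L]], "window_length")
  class(agg) <- c("hrv_windows", "data.frame")
  agg
}

#' Blink-frequency driving fatigue degree
#'
#' The blink analogue of the HRV fatigue degree, built so that both
#' statistics are on the same scale with equal (zero) initial values:
#' blink-DFD_i = (BF_i - BF_initial) / (BF_initial - BF_static), where
#' BF_static is the seated-rest blink rate and BF_initial the rate of the
#' first post-trim driving window(s), in times/min.
#'
#' @param bf Per-window blink frequencies (times/min).
#' @param t Window mid-times (s), same length as `bf`.
#' @param baselines A [compute_baselines()] result carrying `bf_static`
#'   and `bf_initial`, or a list with those two fields.
#' @param window_length Window length in s (metadata only).
#' @return A [dfd_series()] with `source = "blink"`.
#' @export
blink_dfd <- function(bf, t, baselines, window_length = NA_real_) {
  if (is.null(baselines$bf_static) || is.null(baselines$bf_initial))
    stop("blink baselines (bf_static, bf_initial) are required")
  denom <- baselines$bf_initial - baselines$bf_static
  if (abs(denom) <= 1e-6)
    stop("degenerate blink baseline: |BF_initial - BF_static| ~ 0")
  dfd_series(t, (bf - baselines$bf_initial) / denom,
             source = "blink", window_length = window_length)
}

#' Least-squares cubic with diagnostics
#'
#' Internal workhorse shared by the trend and correction-factor fits.  The
#' predictor is centered and scaled before fitting for conditioning; the
#' returned coefficients are mapped back to the original scale.
#'
#' @param x,y Numeric vectors, length >= 5.
#' @param degree Polynomial degree (default 3).
#' @param weights Optional observation weights.
#' @return List: `coef` (length degree+1, original scale, ascending
#'   powers), `fitted`, `rss`, `F`, `sig_F`, `df`, `sigma`, `se_scaled`.
#' @noRd
cubic_ls <- function(x, y, degree = 3L, weights = NULL) {
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < degree + 2L) stop("too few points for a degree-", degree, " fit")
  if (stats::sd(x) == 0) stop("degenerate design: predictor is constant")
  if (stats::sd(y) == 0) {
    ## a flat response: slope terms vanish, overall F is undefined
    return(list(coef = c(y[1], rep(0, degree)), fitted = y, rss = 0,
                F = NA_real_, sig_F = NA_real_,
                df = c(degree, n - degree - 1L), sigma = 0,
                se_scaled = rep(NA_real_, degree + 1L)))
  }
  m <- mean(x); s <- stats::sd(x)
  z <- (x - m) / s
  X <- stats::poly(z, degree = degree, raw = TRUE)
  fit <- if (is.null(weights)) stats::lm(y ~ X)
         else stats::lm(y ~ X, weights = weights)
  a <- unname(stats::coef(fit))
  if (any(!is.finite(a)))
    stop("degenerate design: collinear predictors")
  sm <- quiet_summary(fit)
  fs <- sm$fstatistic
  Fv <- if (is.null(fs)) NA_real_ else unname(fs[1])
  sig <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  list(coef = poly_unscale(a, m, s),
       fitted = unname(stats::fitted(fit)),
       rss = sum(stats::residuals(fit)^2),
       F = Fv, sig_F = unname(sig),
       df = c(degree, n - degree - 1L),
       sigma = sm$sigma,
       se_scaled = unname(sm$coefficients[, "Std. Error"]))
}

## summary.lm warns on exact (zero-residual) fits; those are legitimate
## here (noiseless oracles), so that specific warning is muffled
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

## map coefficients of p(z), z = (x - m)/s, to coefficients in x
poly_unscale <- function(a, m, s) {
  degree <- length(a) - 1L
  out <- numeric(degree + 1L)
  for (j in 0:degree) {
    ## a_j * ((x - m)/s)^j expanded via the binomial theorem
    for (i in 0:j) {
      out[i + 1L] <- out[i + 1L] +
        a[j + 1L] / s^j * choose(j, i) * (-m)^(j - i)
    }
  }
  out
}

#' Fit a cubic trend to a fatigue series
#'
#' Fatigue accumulates along an S-shaped trajectory, so the per-window
#' fatigue series is summarized by a least-squares cubic in time.  The
#' overall regression F statistic and its significance ("significance F",
#' the p value of the regression ANOVA) quantify how well the trend
#' explains the series; the cubic's inflection point is the candidate
#' fatigue-state breakpoint (see [detect_breakpoints()]).
#'
#' @param series A [dfd_series()], or a numeric vector of values if `t`
#'   is given.
#' @param t Optional explicit time vector (s).
#' @return An object of class `trend_model`: `coef` (b0..b3 on the
#'   original time scale), `rss`, `F`, `sig_F`, `df`, `span`,
#'   `inflection_time` (NA when undefined or outside the span), `n`.
#' @examples
#' tt <- seq(0, 7000, by = 120)
#' y <- 1 + 0.01 * tt - 3e-6 * tt^2 + 5e-10 * tt^3
#' fit_trend(dfd_series(tt, y, "hrv", 120))
#' @export
fit_trend <- function(series, t = NULL) {
  if (inherits(series, "dfd_series")) {
    t <- series$t; y <- series$values
  } else {
    y <- as.numeric(series)
    if (is.null(t)) stop("supply a dfd_series or both values and t")
  }
  if (length(y) < 5L) stop("at least 5 points are required for the cubic trend")
  ls <- cubic_ls(t, y, degree = 3L)
  span <- range(t)
  out <- structure(
    list(coef = ls$coef, rss = ls$rss, F = ls$F, sig_F = ls$sig_F,
         df = ls$df, span = span, n = length(y), sigma = ls$sigma),
    class = "trend_model")
  out$inflection_time <- detect_breakpoints(out)
  out
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf(
    "<trend_model> b = (%.4g, %.4g, %.4g, %.4g), F = %.3g, sig F = %.3g\n",
    x$coef[1], x$coef[2], x$coef[3], x$coef[4], x$F, x$sig_F))
  if (is.finite(x$inflection_time))
    cat(sprintf("  inflection at %.1f s\n", x$inflection_time))
  invisible(x)
}

#' Fatigue-state breakpoint of a cubic trend
#'
#' The inflection point of the fitted cubic, t* = -b2 / (3 b3), marks the
#' transition between fatigue states (the curvature of the fatigue
#' trajectory changes sign there).  Reported only when the cubic term is
#' nonzero and t* falls inside the fitted span; absence (NA) is a valid
#' result.
#'
#' @param trend A [fit_trend()] result.
#' @param span Optional length-2 numeric overriding the trend's own span.
#' @return Inflection time in s, or `NA_real_`.
#' @export
detect_breakpoints <- function(trend, span = NULL) {
  stopifnot(inherits(trend, "trend_model"))
  if (is.null(span)) span <- trend$span
  b2 <- trend$coef[3]; b3 <- trend$coef[4]
  if (!is.finite(b3) || b3 == 0) return(NA_real_)
  t_star <- -b2 / (3 * b3)
  if (t_star < span[1] || t_star > span[2]) return(NA_real_)
  t_star
}

#' Select the HRV aggregation window length
#'
#' Recomputes the fatigue series for each candidate window length, fits
#' the cubic trend, and records the regression F statistic and its
#' significance per candidate.  Two selection rules are offered.  The
#' `"default"` rule returns `default_length` provided its trend is
#' significant (significance F < `alpha`), falling back to the smallest-F
#' significant candidate otherwise.  The `"min-F"` rule takes the
#' criterion "the smaller the significance F and F value, the better"
#' literally and returns the significant candidate with the smallest F.
#' The two rules can disagree; [apply_selection_rule()] exposes the rule
#' logic on a precomputed table and the result records both choices so a
#' report can flag the discrepancy.
#'
#' @param rr A trimmed [rri_series()] for the drive.
#' @param rrvc_static Static-baseline RRVC (the initial baseline is
#'   recomputed per candidate from that candidate's first `k` windows).
#' @param candidates Candidate window lengths in s
#'   (default c(30, 60, 120, 180, 240, 300)).
#' @param rule `"default"` or `"min-F"`.
#' @param default_length Preferred length for the `"default"` rule (120 s).
#' @param alpha Significance threshold (0.05).
#' @param k,min_beats Passed through to [compute_baselines()] /
#'   [window_hrv()].
#' @return List of class `window_selection`: `chosen` (s), `rule`,
#'   `table` (data frame `length_s, F, sig_F, n_windows`),
#'   `chosen_default`, `chosen_min_F`, `rules_agree`.
#' @export
select_window_length <- function(rr, rrvc_static,
                                 candidates = c(30, 60, 120, 180, 240, 300),
                                 rule = c("default", "min-F"),
                                 default_length = 120, alpha = 0.05,
                                 k = 1, min_beats = 10) {
  rule <- match.arg(rule)
  rows <- lapply(candidates, function(L) {
    res <- try({
      w <- window_hrv(rr, window_length = L, min_beats = min_beats)
      bl <- compute_baselines(w, rrvc_static = rrvc_static, k = k)
      fm <- compute_fatigue_metrics(w, bl)
      tr <- fit_trend(fm$dfd)
      data.frame(length_s = L, F = tr$F, sig_F = tr$sig_F,
                 n_windows = tr$n)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(length_s = L, F = NA_real_, sig_F = NA_real_,
                 n_windows = NA_integer_)
    else res
  })
  tab <- do.call(rbind, rows)
  finish_selection(tab, rule, default_length, alpha)
}

#' Apply a window-selection rule to a precomputed table
#'
#' The rule logic of [select_window_length()] applied to an existing table
#' of per-candidate regression statistics (e.g. one computed elsewhere).
#'
#' @param table Data frame with columns `length_s`, `F`, `sig_F`.
#' @inheritParams select_window_length
#' @return Same structure as [select_window_length()].
#' @examples
#' tab <- data.frame(length_s = c(30, 60, 120, 180, 240, 300),
#'                   sig_F = c(0.009, 0.011, 0.012, 0.022, 0.103, 0.142),
#'                   F = c(112.6, 82.2, 54.7, 45.3, 38.9, 21.8))
#' apply_selection_rule(tab, "default")$chosen  # 120
#' apply_selection_rule(tab, "min-F")$chosen    # 180
#' @export
apply_selection_rule <- function(table, rule = c("default", "min-F"),
                                 default_length = 120, alpha = 0.05) {
  rule <- match.arg(rule)
  stopifnot(all(c("length_s", "F", "sig_F") %in% names(table)))
  finish_selection(table, rule, default_length, alpha)
}

finish_selection <- function(tab, rule, default_length, alpha) {
  sig <- !is.na(tab$sig_F) & tab$sig_F < alpha
  if (!any(sig)) {
    msg <- paste0(
      "no candidate window achieves significance < ", alpha, ":\n",
      paste(utils::capture.output(print(tab)), collapse = "\n"))
    cond <- structure(class = c("rdfd_no_significant_window", "error",
                                "condition"),
                      list(message = msg, call = sys.call(-1), table = tab))
    stop(cond)
  }
  min_f <- tab$length_s[sig][which.min(tab$F[sig])]
  chosen_default <- if (default_length %in% tab$length_s[sig])
    default_length else min_f
  chosen <- if (rule == "default") chosen_default else min_f
  structure(
    list(chosen = chosen, rule = rule, table = tab,
         chosen_default = chosen_default, chosen_min_F = min_f,
         rules_agree = chosen_default == min_f),
    class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat(sprintf("<window_selection> chosen %g s (rule %s)\n", x$chosen, x$rule))
  print(x$table, row.names = FALSE)
  if (!x$rules_agree)
    cat(sprintf(
      "note: rules disagree (default rule -> %g s, min-F rule -> %g s)\n",
      x$chosen_default, x$chosen_min_F))
  invisible(x)
}
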