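#' Calibrate per-slope correction models and revise a fatigue series
#'
#' The core correction workflow on window-level series: estimate
#' pointwise correction factors against the blink reference, calibrate a
#' cubic-in-altitude model per slope class (or a single model when no
#' segmentation is given), and apply the correction to the HRV fatigue
#' series.  Up- and downslope models are calibrated on disjoint window
#' sets; flat segments use delta = 1 unless enough pairs support a model.
#'
#' @param hrv,blink [dfd_series()] objects on a common window grid.
#' @param altitude An [altitude_profile()] or altitudes (m) at the hrv
#'   window mid-times.
#' @param segments Optional [classify_slope()] result; when supplied,
#'   calibration is per slope class.
#' @param epsilon Zero-crossing guard for [pointwise_delta()] (0.05).
#' @param degree Polynomial degree of the correction model (3).
#' @param min_span Minimum altitude span per model, m (200).
#' @return List: `revised` ([dfd_series()]), `models` (named list of
#'   `delta_model`s), `pairs` (the pointwise estimates with slope class),
#'   `n_excluded`.
#' @export
calibrate_and_revise <- function(hrv, blink, altitude, segments = NULL,
                                 epsilon = 0.05, degree = 3L,
                                 min_span = 200) {
  h_w <- if (inherits(altitude, "altitude_profile"))
    altitude_at(altitude, hrv$t) else altitude
  pairs <- pointwise_delta(blink, hrv, h_w, epsilon = epsilon)
  if (is.null(segments)) {
    model <- calibrate_delta(pairs, slope_class = "up", degree = degree,
                             min_span = min_span)
    revised <- revise_dfd(hrv, model, h_w)
    return(list(revised = revised, models = list(all = model),
                pairs = pairs, n_excluded = attr(pairs, "n_excluded")))
  }
  pairs$slope_class <- slope_class_at(segments, pairs$t)
  models <- list()
  for (cl in unique(pairs$slope_class)) {
    sub <- pairs[pairs$slope_class == cl, , drop = FALSE]
    fit <- try(calibrate_delta(sub, slope_class = cl, degree = degree,
                               min_span = min_span), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      models[[cl]] <- fit
    } else if (cl != "flat") {
      stop("cannot calibrate slope class '", cl, "': ",
           attr(fit, "condition")$message)
    }  # flat class without support falls back to delta = 1 in revise_dfd
  }
  revised <- revise_dfd(hrv, models, h_w, segments = segments)
  list(revised = revised, models = models, pairs = pairs,
       n_excluded = attr(pairs, "n_excluded"))
}

#' Run the full fatigue-estimation pipeline
#'
#' Executes every stage on raw recordings: ingest, excitement-period
#' trim, HRV windowing, baseline computation, HRV- and blink-based
#' fatigue series, slope segmentation, correction-factor calibration,
#' fatigue revision, cubic trend fits with breakpoints, and curve
#' agreement statistics for the uncorrected and revised series against
#' the blink reference.
#'
#' @param rr An [rri_series()] for the drive, or an R-R CSV path.
#' @param blinks A [blink_series()] or blink CSV path.
#' @param altitude An [altitude_profile()] or altitude CSV path.
#' @param static_rr Optional seated-rest [rri_series()] or CSV path;
#'   alternatively give `rrvc_static`.
#' @param rrvc_static Scalar static RRVC baseline.
#' @param bf_static Seated-rest blink rate, times/min (required for the
#'   blink reference).
#' @param window_length HRV window length in s (default 120).
#' @param trim Excitement trim in s at each end (default 1000).
#' @param k Leading windows defining the initial baselines (default 1).
#' @param min_beats Minimum beats per usable window (default 10).
#' @param epsilon_delta Zero-crossing guard for calibration (0.05).
#' @param degree Correction-polynomial degree (3).
#' @param segment_slopes Classify slopes and calibrate per class
#'   (default TRUE).
#' @param select_window Also compute the window-length selection table
#'   (default FALSE; uses `window_length` as the default-rule preference).
#' @param candidates Candidate window lengths for selection.
#' @return A list of class `rdfd_report`; see Details.  Key entries:
#'   `dfd` (named [dfd_series()] list: hrv, blink, revised), `baselines`,
#'   `windows`, `segments`, `models`, `trends`, `breakpoints`,
#'   `agreement` (list of [curve_agreement()]: dfd_vs_blink,
#'   rdfd_vs_blink), `window_selection` (if requested), `exclusions`.
#' @export
run_pipeline <- function(rr, blinks, altitude,
                         static_rr = NULL, rrvc_static = NULL,
                         bf_static, window_length = 120, trim = 1000,
                         k = 1, min_beats = 10, epsilon_delta = 0.05,
                         degree = 3L, segment_slopes = TRUE,
                         select_window = FALSE,
                         candidates = c(30, 60, 120, 180, 240, 300)) {
  if (is.character(rr)) rr <- read_rr_csv(rr)
  if (is.character(blinks)) blinks <- read_blink_csv(blinks)
  if (is.character(altitude)) altitude <- read_altitude_csv(altitude)
  if (is.character(static_rr)) static_rr <- read_rr_csv(static_rr)
  stopifnot(inherits(rr, "rri_series"), inherits(blinks, "blink_series"),
            inherits(altitude, "altitude_profile"))

  span <- range(rr$beat_times)
  rr_t <- trim_excitement(rr, trim, trim, span = span)
  blinks_t <- trim_excitement(blinks, trim, trim, span = span)

  windows <- window_hrv(rr_t, window_length = window_length,
                        min_beats = min_beats)
  wb <- cbind(windows$start, windows$end)
  bf <- blink_frequency(blinks_t, wb)
  use1 <- which(windows$usable)[seq_len(k)]
  baselines <- compute_baselines(
    windows, static_rr = static_rr, rrvc_static = rrvc_static, k = k,
    bf_static = bf_static, bf_initial = mean(bf[use1]))

  metrics <- compute_fatigue_metrics(windows, baselines)
  hrv_dfd <- metrics$dfd
  b_dfd <- blink_dfd(bf[windows$usable], windows$t_mid[windows$usable],
                     baselines, window_length = window_length)

  segments <- if (segment_slopes) classify_slope(altitude) else NULL
  corr <- calibrate_and_revise(hrv_dfd, b_dfd, altitude,
                               segments = segments,
                               epsilon = epsilon_delta, degree = degree)

  trends <- list(hrv = fit_trend(hrv_dfd), blink = fit_trend(b_dfd),
                 revised = fit_trend(corr$revised))
  breakpoints <- vapply(trends, function(tr) tr$inflection_time, numeric(1))

  agreement <- list(dfd_vs_blink = curve_agreement(hrv_dfd, b_dfd),
                    rdfd_vs_blink = curve_agreement(corr$revised, b_dfd))

  selection <- if (select_window) {
    stat <- if (!is.null(rrvc_static)) rrvc_static else baselines$rrvc_static
    try(select_window_length(rr_t, rrvc_static = stat,
                             candidates = candidates,
                             default_length = window_length,
                             k = k, min_beats = min_beats),
        silent = TRUE)
  } else NULL

  structure(
    list(params = list(window_length = window_length, trim = trim, k = k,
                       min_beats = min_beats, epsilon_delta = epsilon_delta,
                       degree = degree),
         windows = windows, baselines = baselines,
         dfd = list(hrv = hrv_dfd, blink = b_dfd, revised = corr$revised),
         segments = segments, models = corr$models,
         pairs = corr$pairs,
         trends = trends, breakpoints = breakpoints,
         agreement = agreement,
         window_selection = selection,
         exclusions = list(
           low_beat_windows = windows$i[!windows$usable],
           calibration_excluded = corr$n_excluded)),
    class = "rdfd_report")
}

#' @export
print.rdfd_report <- function(x, ...) {
  cat("<rdfd_report>\n")
  cat(sprintf("  %d windows of %g s, BDF %.5f\n",
              nrow(x$windows), x$params$window_length, x$baselines$bdf))
  if (!is.null(x$segments))
    cat(sprintf("  slope segments: %s\n",
                paste(x$segments$slope_class, collapse = ", ")))
  cat("  agreement with the blink reference:\n")
  print(compare_report(x$agreement), row.names = FALSE)
  bp <- x$breakpoints
  bp <- bp[is.finite(bp)]
  if (length(bp))
    cat(sprintf("  fatigue breakpoints: %s\n",
                paste(sprintf("%s %.0f s", names(bp), bp), collapse = ", ")))
  invisible(x)
}

#' Tabulate curve-agreement statistics
#'
#' Formats a set of [curve_agreement()] results as one table with the
#' sum of squared differences, regression F, significance F and R^2 per
#' compared pair.
#'
#' @param pairs Named list of [curve_agreement()] objects.
#' @return Data frame with columns `comparison, ss, F, sig_F, r2, n`.
#' @export
compare_report <- function(pairs) {
  if (length(pairs) == 0L) stop("no comparisons supplied")
  lab <- names(pairs)
  if (is.null(lab)) lab <- paste0("pair_", seq_along(pairs))
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    stopifnot(inherits(p, "curve_agreement"))
    data.frame(comparison = lab[i], ss = p$ss, F = p$F, sig_F = p$sig_F,
               r2 = p$r2, n = p$n)
  }))
}

#' Write a fatigue table as CSV
#'
#' Writes the per-window fatigue table (`i, t_mid_s, M_ms, SDNN_ms, RRVC,
#' FC, DFC, DFD`) at full double precision.
#'
#' @param report An `rdfd_report` or `fatigue_metrics` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dfd_csv <- function(report, path) {
  if (inherits(report, "rdfd_report")) {
    w <- report$windows[report$windows$usable, , drop = FALSE]
    m <- report$dfd$hrv
    bl <- report$baselines
    tab <- data.frame(i = w$i, t_mid_s = w$t_mid, M_ms = w$M,
                      SDNN_ms = w$SDNN, RRVC = w$RRVC,
                      FC = w$RRVC - bl$rrvc_static,
                      DFC = w$RRVC - bl$rrvc_initial,
                      DFD = m$values)
  } else if (inherits(report, "fatigue_metrics")) {
    tab <- report$table
    names(tab) <- c("i", "t_mid_s", "M_ms", "SDNN_ms", "RRVC",
                    "FC", "DFC", "DFD")
  } else stop("unsupported object")
  utils::write.csv(format(tab, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
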