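#' Detect R peaks in an ECG trace
#'
#' A Pan-Tompkins-style QRS detector: band-pass filter (default 5-15 Hz,
#' zero-phase Butterworth), squared derivative, moving-window integration,
#' and an adaptive amplitude threshold, followed by a refractory rule that
#' forbids two detections closer than `min_rr_s`.  Each detection is then
#' refined to the local maximum of the lightly smoothed raw signal so the
#' reported time lands on the R wave apex rather than on the integrated
#' envelope.
#'
#' @param ecg An [ecg_trace()]; sampling rate must be at least 100 Hz.
#' @param config List of detector parameters.  Recognized entries (with
#'   defaults): `min_rr_s` (0.3) refractory period in s; `band` (c(5, 15))
#'   pass band in Hz; `integration_s` (0.15) integration window in s;
#'   `threshold_frac` (0.25) threshold as a fraction of the upper envelope
#'   level; `refine_s` (0.1) half-width of the apex refinement window;
#'   `refine_smooth_s` (0.02) smoothing window used during refinement.
#' @return Strictly increasing numeric vector of peak times (s).
#' @examples
#' rr <- rri_series(beat_times = 1:30, intervals = rep(1000, 30))
#' ecg <- gen_ecg(rr, sampling_rate = 250)
#' peaks <- detect_r_peaks(ecg)
#' @export
detect_r_peaks <- function(ecg, config = list()) {
  stopifnot(inherits(ecg, "ecg_trace"))
  cfg <- utils::modifyList(
    list(min_rr_s = 0.3, band = c(5, 15), integration_s = 0.15,
         threshold_frac = 0.25, refine_s = 0.1, refine_smooth_s = 0.02),
    config)
  fs <- ecg$sampling_rate
  if (fs < 100)
    stop("sampling rate below 100 Hz: insufficient signal")
  x <- ecg$samples
  n <- length(x)
  if (n / fs < 2 * cfg$min_rr_s)
    stop("insufficient signal: trace shorter than two expected beats")

  ## band-pass (zero phase, so no group-delay compensation needed)
  bf <- signal::butter(2, cfg$band / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  ## squared derivative emphasizes the steep QRS slopes
  d <- c(0, diff(xb)) * fs
  e <- d^2
  ## moving-window integration
  wi <- max(1L, round(cfg$integration_s * fs))
  z <- stats::filter(e, rep(1 / wi, wi), sides = 2)
  z[is.na(z)] <- 0
  z <- as.numeric(z)

  top <- stats::quantile(z, 0.98, names = FALSE)
  if (!is.finite(top) || top <= .Machine$double.eps)
    stop("no QRS detected")
  thr <- cfg$threshold_frac * top

  ## candidate local maxima of the envelope above threshold
  above <- z > thr
  loc_max <- c(FALSE, diff(z) > 0) & c(diff(z) <= 0, FALSE)
  cand <- which(above & loc_max)
  if (length(cand) == 0L) stop("no QRS detected")

  ## refractory rule: keep the strongest candidate within min_rr_s
  min_gap <- cfg$min_rr_s * fs
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0L || i - kept[length(kept)] >= min_gap) {
      kept <- c(kept, i)
    } else if (z[i] > z[kept[length(kept)]]) {
      kept[length(kept)] <- i
    }
  }

  ## refine to the apex of the smoothed raw signal
  ws <- max(1L, round(cfg$refine_smooth_s * fs))
  xs <- stats::filter(x, rep(1 / ws, ws), sides = 2)
  xs[is.na(xs)] <- x[is.na(xs)]
  xs <- as.numeric(xs)
  half <- as.integer(max(1, round(cfg$refine_s * fs)))
  peaks_idx <- vapply(kept, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(xs[lo:hi]) - 1L
  }, numeric(1))
  peaks_idx <- sort(unique(peaks_idx))
  ## a second refractory pass: refinement can pull two envelope candidates
  ## onto nearby apices
  if (length(peaks_idx) > 1L) {
    ok <- c(TRUE, diff(peaks_idx) >= min_gap)
    peaks_idx <- peaks_idx[ok]
  }
  ecg$start_time + (peaks_idx - 1L) / fs
}

#' Build an R-R interval series from peak times
#'
#' The R-R interval is the time difference between adjacent R wave peaks,
#' expressed in milliseconds; `n` peaks yield `n - 1` intervals, each
#' stamped with the time of its closing beat.
#'
#' @param peaks Strictly increasing peak times (s), length >= 2.
#' @return An [rri_series()].
#' @examples
#' rr_from_peaks(c(0, 1.0, 2.01))  # intervals 1000, 1010 ms
#' @export
rr_from_peaks <- function(peaks) {
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2L)
    stop("at least 2 peaks are required")
  if (any(diff(peaks) <= 0))
    stop("peak times must be strictly increasing")
  rri_series(beat_times = peaks[-1L], intervals = diff(peaks) * 1000)
}

#' Remove artifact beats from an R-R series
#'
#' Two rules, applied in one pass: an interval is dropped if it falls
#' outside the physiological bounds, or if it differs from the previous
#' *retained* interval by more than `jump_fraction` of that interval
#' (ectopic-beat jumps).  The first in-bounds interval is always retained.
#' The output intervals are a subsequence of the input intervals.
#'
#' @param rr An [rri_series()].
#' @param bounds Length-2 numeric, physiological bounds in ms
#'   (default c(300, 2000)).
#' @param jump_fraction Maximum allowed relative jump between consecutive
#'   retained intervals (default 0.2).
#' @return An [rri_series()] with attribute `n_removed`.
#' @export
clean_rr <- function(rr, bounds = c(300, 2000), jump_fraction = 0.2) {
  stopifnot(inherits(rr, "rri_series"), length(bounds) == 2L,
            bounds[1] < bounds[2], jump_fraction > 0)
  keep <- logical(length(rr$intervals))
  prev <- NA_real_
  for (k in seq_along(rr$intervals)) {
    x <- rr$intervals[k]
    ok <- x >= bounds[1] && x <= bounds[2] &&
      (is.na(prev) || abs(x - prev) / prev <= jump_fraction)
    keep[k] <- ok
    if (ok) prev <- x
  }
  if (!any(keep)) stop("no usable beats after artifact removal")
  out <- rri_series(rr$beat_times[keep], rr$intervals[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trim the excitement periods from a series
#'
#' Drivers show unreasonably elevated heart rate during the first and last
#' stretch of a drive (the "excitement period"); analysis therefore drops
#' the first and last 1000 s by default.  Works on any of the package's
#' time-stamped series types and returns the same type.
#'
#' @param x An [rri_series()], [blink_series()], [altitude_profile()] or
#'   [dfd_series()].
#' @param head_s,tail_s Seconds removed from the start and end
#'   (defaults 1000 each).
#' @param span Optional length-2 numeric giving the recording span
#'   \[t_start, t_end\] in s; defaults to the range of the series' own
#'   time stamps.
#' @return Object of the same class restricted to
#'   \[t_start + head_s, t_end - tail_s\].
#' @export
trim_excitement <- function(x, head_s = 1000, tail_s = 1000, span = NULL) {
  UseMethod("trim_excitement")
}

trim_span <- function(times, head_s, tail_s, span) {
  if (is.null(span)) span <- range(times)
  if (head_s < 0 || tail_s < 0) stop("trim lengths must be nonnegative")
  lo <- span[1] + head_s
  hi <- span[2] - tail_s
  if (hi <= lo) stop("trim exceeds recording")
  times >= lo & times <= hi
}

#' @export
trim_excitement.rri_series <- function(x, head_s = 1000, tail_s = 1000,
                                       span = NULL) {
  keep <- trim_span(x$beat_times, head_s, tail_s, span)
  if (!any(keep)) stop("trim exceeds recording: no beats retained")
  rri_series(x$beat_times[keep], x$intervals[keep])
}

#' @export
trim_excitement.blink_series <- function(x, head_s = 1000, tail_s = 1000,
                                         span = NULL) {
  if (is.null(span) && length(x$blink_times) == 0L)
    stop("cannot infer span of an empty blink series; supply `span`")
  keep <- trim_span(x$blink_times, head_s, tail_s, span)
  blink_series(x$blink_times[keep])
}

#' @export
trim_excitement.altitude_profile <- function(x, head_s = 1000, tail_s = 1000,
                                             span = NULL) {
  keep <- trim_span(x$times, head_s, tail_s, span)
  if (!any(keep)) stop("trim exceeds recording")
  altitude_profile(x$times[keep], x$altitudes[keep])
}

#' @export
trim_excitement.dfd_series <- function(x, head_s = 1000, tail_s = 1000,
                                       span = NULL) {
  keep <- trim_span(x$t, head_s, tail_s, span)
  if (!any(keep)) stop("trim exceeds recording")
  dfd_series(x$t[keep], x$values[keep], x$source, x$window_length)
}

#' Blink frequency per window
#'
#' Counts blink events in each half-open window \[start, end) and divides
#' by the window length in minutes, giving the field's standard unit of
#' times/min.  Simultaneous blink events each count.
#'
#' @param blinks A [blink_series()].
#' @param windows Two-column matrix or data frame of window \[start, end)
#'   boundaries in s; windows must be ordered and non-overlapping.
#' @return Numeric vector of rates (times/min), one per window.
#' @examples
#' b <- blink_series(seq(1, 119, by = 4))
#' blink_frequency(b, cbind(0, 120))   # 30 blinks / 2 min = 15 times/min
#' @export
blink_frequency <- function(blinks, windows) {
  stopifnot(inherits(blinks, "blink_series"))
  w <- as.matrix(windows)
  if (ncol(w) != 2L) stop("windows must have two columns (start, end)")
  if (any(w[, 2] <= w[, 1])) stop("zero-length or inverted window")
  if (nrow(w) > 1L && any(w[-1L, 1] < w[-nrow(w), 2]))
    stop("windows must be ordered and non-overlapping")
  vapply(seq_len(nrow(w)), function(i) {
    cnt <- sum(blinks$blink_times >= w[i, 1] & blinks$blink_times < w[i, 2])
    cnt / ((w[i, 2] - w[i, 1]) / 60)
  }, numeric(1))
}

#' Read series from CSV
#'
#' Plain-CSV readers for the package's input formats.  Required columns:
#' R-R series `time_s, rr_ms`; ECG `time_s, mv` (sampling rate passed
#' separately); blinks `blink_time_s`; altitude `time_s, altitude_m`.
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling rate in Hz (ECG only); if `NULL` it is
#'   inferred from the median time step.
#' @return The corresponding series object.
#' @name read_series_csv
NULL

check_input_file <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  path
}

#' @rdname read_series_csv
#' @export
read_rr_csv <- function(path) {
  d <- utils::read.csv(check_input_file(path))
  if (!all(c("time_s", "rr_ms") %in% names(d)))
    stop("R-R CSV must have columns time_s, rr_ms")
  rri_series(d$time_s, d$rr_ms)
}

#' @rdname read_series_csv
#' @export
read_ecg_csv <- function(path, sampling_rate = NULL) {
  d <- utils::read.csv(check_input_file(path))
  if (!all(c("time_s", "mv") %in% names(d)))
    stop("ECG CSV must have columns time_s, mv")
  if (is.null(sampling_rate))
    sampling_rate <- 1 / stats::median(diff(d$time_s))
  ecg_trace(d$mv, sampling_rate, start_time = d$time_s[1])
}

#' @rdname read_series_csv
#' @export
read_blink_csv <- function(path) {
  d <- utils::read.csv(check_input_file(path))
  if (!"blink_time_s" %in% names(d))
    stop("blink CSV must have column blink_time_s")
  blink_series(d$blink_time_s)
}

#' @rdname read_series_csv
#' @export
read_altitude_csv <- function(path) {
  d <- utils::read.csv(check_input_file(path))
  if (!all(c("time_s", "altitude_m") %in% names(d)))
    stop("altitude CSV must have columns time_s, altitude_m")
  altitude_profile(d$time_s, d$altitude_m)
}
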