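#' Construct an ECG trace
#'
#' A thin container for a single-channel ECG recording: a regularly sampled
#' amplitude sequence in millivolts with a sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes (mV); all finite, length >= 2.
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `ecg_trace` with fields `samples`,
#'   `sampling_rate`, `start_time`.
#' @examples
#' ecg <- ecg_trace(sin(seq(0, 2 * pi, length.out = 500)), sampling_rate = 250)
#' @export
ecg_trace <- function(samples, sampling_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("ECG trace must contain at least 2 samples")
  if (!all(is.finite(samples)))
    stop("ECG samples must all be finite")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number (Hz)")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time)),
    class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<ecg_trace> %d samples @ %g Hz (%.1f s), start %g s\n",
              length(x$samples), x$sampling_rate, dur, x$start_time))
  invisible(x)
}

#' Construct an R-R interval series
#'
#' Holds the beat-to-beat heart period series: beat times in seconds and the
#' corresponding R-R intervals in milliseconds.  The interval ending at beat
#' time `beat_times[k]` is `intervals[k]`; interval/beat-time consistency is
#' enforced when both are derived from peaks (see [rr_from_peaks()]), but a
#' cleaned series is allowed to be an irregular subsequence, so beat times
#' only need to be strictly increasing.
#'
#' @param beat_times Strictly increasing beat times in seconds.  Each entry
#'   is the time of the beat that *closes* the corresponding interval.
#' @param intervals R-R intervals in milliseconds, same length as
#'   `beat_times`; all positive.
#' @return An object of class `rri_series`.
#' @seealso [rr_from_peaks()], [clean_rr()], [window_hrv()]
#' @export
rri_series <- function(beat_times, intervals) {
  beat_times <- as.numeric(beat_times)
  intervals <- as.numeric(intervals)
  if (length(beat_times) != length(intervals))
    stop("beat_times and intervals must have equal length")
  if (length(beat_times) == 0L)
    stop("empty R-R series")
  if (any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all R-R intervals must be finite and positive")
  structure(list(beat_times = beat_times, intervals = intervals),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf(
    "<rri_series> %d intervals, span [%.1f, %.1f] s, mean %.1f ms\n",
    length(x$intervals), x$beat_times[1], x$beat_times[length(x$beat_times)],
    mean(x$intervals)))
  invisible(x)
}

#' Construct a blink event series
#'
#' @param blink_times Nondecreasing blink event times in seconds
#'   (simultaneous events are allowed).
#' @return An object of class `blink_series`.
#' @export
blink_series <- function(blink_times) {
  blink_times <- as.numeric(blink_times)
  if (length(blink_times) > 1L && any(diff(blink_times) < 0))
    stop("blink_times must be nondecreasing")
  if (any(!is.finite(blink_times)))
    stop("blink_times must be finite")
  structure(list(blink_times = blink_times), class = "blink_series")
}

#' @export
print.blink_series <- function(x, ...) {
  cat(sprintf("<blink_series> %d blinks\n", length(x$blink_times)))
  invisible(x)
}

#' Construct an altitude profile
#'
#' @param times Strictly increasing times in seconds.
#' @param altitudes Altitudes in metres, same length as `times`; must lie in
#'   \[0, 9000\] m.
#' @return An object of class `altitude_profile`.
#' @export
altitude_profile <- function(times, altitudes) {
  times <- as.numeric(times)
  altitudes <- as.numeric(altitudes)
  if (length(times) != length(altitudes))
    stop("times and altitudes must have equal length")
  if (length(times) == 0L) stop("empty altitude profile")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(altitudes)) || any(altitudes < 0) || any(altitudes > 9000))
    stop("altitudes must be finite and within [0, 9000] m")
  structure(list(times = times, altitudes = altitudes),
            class = "altitude_profile")
}

#' @export
print.altitude_profile <- function(x, ...) {
  cat(sprintf("<altitude_profile> %d points, %.0f-%.0f m over [%.0f, %.0f] s\n",
              length(x$times), min(x$altitudes), max(x$altitudes),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Interpolate an altitude profile at arbitrary times
#'
#' Linear interpolation within the profile span; constant extension beyond
#' the endpoints.
#'
#' @param profile An [altitude_profile()].
#' @param t Times (s) at which to evaluate.
#' @return Numeric vector of altitudes (m).
#' @export
altitude_at <- function(profile, t) {
  stopifnot(inherits(profile, "altitude_profile"))
  if (length(profile$times) == 1L)
    return(rep(profile$altitudes, length(t)))
  stats::approx(profile$times, profile$altitudes, xout = t, rule = 2)$y
}

#' Construct a DFD (driving fatigue degree) series
#'
#' One fatigue value per aggregation window, indexed by window mid-time.
#' `source` records which signal produced it: `"hrv"` for the R-R interval
#' statistic, `"blink"` for the blink-frequency analogue, `"revised"` for
#' the altitude-corrected product.
#'
#' @param t Window mid-times in seconds, strictly increasing.
#' @param values Dimensionless fatigue values, same length as `t`.
#' @param source One of `"hrv"`, `"blink"`, `"revised"`.
#' @param window_length Aggregation window length in seconds.
#' @return An object of class `dfd_series`.
#' @export
dfd_series <- function(t, values, source = c("hrv", "blink", "revised"),
                       window_length = NA_real_) {
  source <- match.arg(source)
  t <- as.numeric(t); values <- as.numeric(values)
  if (length(t) != length(values))
    stop("t and values must have equal length")
  if (length(t) == 0L) stop("empty DFD series")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("window times must be strictly increasing")
  if (any(!is.finite(values))) stop("DFD values must be finite")
  structure(list(t = t, values = values, source = source,
                 window_length = as.numeric(window_length)),
            class = "dfd_series")
}

#' @export
print.dfd_series <- function(x, ...) {
  cat(sprintf("<dfd_series source=%s> %d windows (%g s), range [%.3g, %.3g]\n",
              x$source, length(x$t), x$window_length,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.dfd_series <- function(x, ...) {
  data.frame(t_mid_s = x$t, dfd = x$values, source = x$source)
}
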