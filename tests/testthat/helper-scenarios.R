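# shared fixtures, all generated in code

# regular R-R series: constant interval (ms), n beats, starting at t0
regular_rr <- function(interval_ms = 1000, n = 60, t0 = 0) {
  rri_series(t0 + cumsum(rep(interval_ms / 1000, n)), rep(interval_ms, n))
}

# the calibration scenario: 100 post-trim windows climbing the full
# 3540-4768 m study range, with fatigue already accumulated over the span
# so no window sits near the DFD zero crossing
calibration_config <- function(dfd_noise = 0.05) {
  scenario_config(duration = 14000,
                  altitude_knots_t = c(0, 14000),
                  altitude_knots_h = c(3540, 4768),
                  fatigue_midpoint = 3000, fatigue_scale = 1500,
                  dfd_noise = dfd_noise)
}

# match detected peak times against planted beats within tol seconds;
# returns c(recall, precision)
match_peaks <- function(detected, planted, tol) {
  tp <- sum(vapply(planted, function(b) any(abs(detected - b) <= tol),
                   logical(1)))
  c(recall = tp / length(planted), precision = tp / length(detected))
}

# brute-force per-window HRV oracle: direct formulas over the intervals
# falling in each [start, end) window (by closing-beat time)
oracle_windows <- function(rr, window_length, origin = rr$beat_times[1]) {
  t_end <- max(rr$beat_times)
  n_win <- floor((t_end - origin) / window_length)
  if (t_end > origin + n_win * window_length) n_win <- n_win + 1L
  do.call(rbind, lapply(seq_len(n_win), function(i) {
    s <- origin + (i - 1) * window_length
    iv <- rr$intervals[rr$beat_times >= s & rr$beat_times < s + window_length]
    data.frame(i = i, n = length(iv),
               M = if (length(iv)) mean(iv) else NA_real_,
               SDNN = if (length(iv) > 1) sd(iv) else
                 if (length(iv) == 1) 0 else NA_real_)
  }))
}
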