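# Smooth-pursuit metrics: target kinematics, sample exclusion, instantaneous
# velocity gain with trimming, and pursuit saccade counts.

#' Sinusoidal pursuit target position and velocity
#'
#' The target moves along the trial axis as `A * sin(2*pi*f*t)`, starting at
#' the centre, with half-range `A` = 10 deg and `f` = 0.25 Hz by default
#' (10 s trial = 2.5 cycles); velocity is the analytic derivative.
#'
#' @param trial trial record with `pursuit_axis` (`"horizontal"` /
#'   `"vertical"`), `pursuit_freq_hz`, `pursuit_amplitude_deg`.
#' @param t_ms sample times in ms (trial time zero = movement start).
#' @return data.frame with `pos` (deg) and `vel` (deg/s) along the axis.
#' @export
target_kinematics <- function(trial, t_ms) {
  A <- trial$pursuit_amplitude_deg
  f <- trial$pursuit_freq_hz
  w <- 2 * pi * f
  ts <- t_ms / 1000
  data.frame(pos = A * sin(w * ts), vel = A * w * cos(w * ts))
}

#' Per-sample keep/drop mask for pursuit gain
#'
#' Samples inside any saccade, blink or invalid span, padded by `pad_ms`
#' (50 ms) on either side, are dropped.
#'
#' @param tr a [gaze_trace()].
#' @param saccades a [saccade_events()] table.
#' @param blinks data.frame from [detect_blinks()] (already padded).
#' @param pad_ms padding applied to saccade spans, ms.
#' @return logical vector, `TRUE` = keep.
#' @export
exclusion_mask <- function(tr, saccades, blinks, pad_ms = 50) {
  iv <- as_interval_matrix(saccades[, c("onset_ms", "offset_ms")])
  if (nrow(iv)) {
    iv[, 1L] <- iv[, 1L] - pad_ms
    iv[, 2L] <- iv[, 2L] + pad_ms
  }
  iv <- rbind(iv, as_interval_matrix(blinks[, c("onset_ms", "offset_ms")]))
  drop <- points_in_intervals(tr$t, iv) | !tr$valid
  !drop
}

#' Instantaneous pursuit gain samples
#'
#' Signed along-axis eye velocity divided by target velocity, per retained
#' sample. Samples where |target velocity| falls below `min_target_speed`
#' (near the sinusoid's turnarounds, where the ratio is unbounded) are
#' additionally dropped; 0 reproduces the literal ratio everywhere.
#'
#' @param tr a [gaze_trace()].
#' @param trial pursuit trial record.
#' @param mask logical keep mask from [exclusion_mask()].
#' @param min_target_speed deg/s (default 2).
#' @param smooth_window pre-smoothing for the velocity estimate (3 samples
#'   by default; the per-sample ratio is noise-sensitive near turnarounds).
#' @return numeric vector of gain samples (finite, unordered-trim pending).
#' @export
instantaneous_gain <- function(tr, trial, mask, min_target_speed = 2,
                               smooth_window = 3) {
  kin <- estimate_kinematics(tr, smooth_window = smooth_window)
  tk <- target_kinematics(trial, tr$t)
  eye_v <- if (identical(trial$pursuit_axis, "vertical")) kin$vy else kin$vx
  ok <- mask & !is.na(eye_v) & abs(tk$vel) >= min_target_speed
  eye_v[ok] / tk$vel[ok]
}

#' Trim pursuit-gain samples to [-1, +2]
#'
#' @param gain_samples numeric vector.
#' @param lo,hi inclusive retention bounds (defaults -1 and +2).
#' @return list: `retained` gains, `trimmed_fraction`.
#' @export
trim_gain <- function(gain_samples, lo = -1, hi = 2) {
  g <- gain_samples[is.finite(gain_samples)]
  keep <- g >= lo & g <= hi
  list(retained = g[keep],
       trimmed_fraction = if (length(g)) mean(!keep) else 0)
}

#' Count pursuit saccades
#'
#' Saccades with amplitude strictly greater than 2 deg, not containing a
#' blink.
#'
#' @param saccades a [saccade_events()] table.
#' @param min_amplitude threshold, strict.
#' @return integer count.
#' @export
count_pursuit_saccades <- function(saccades, min_amplitude = 2) {
  s <- as.data.frame(saccades)
  sum(s$amplitude > min_amplitude & !s$contains_blink)
}

#' Analyse one pursuit trial end to end
#'
#' @param tr a [gaze_trace()].
#' @param trial pursuit trial record.
#' @param params a [parser_params()] list.
#' @param cfg configuration list for trim bounds and turnaround threshold.
#' @return list: `trial_id`, `axis`, `gain_samples`, `mean_gain`,
#'   `n_saccades`, `excluded_fraction`.
#' @export
pursuit_trial_result <- function(tr, trial, params = parser_params(),
                                 cfg = default_config()) {
  ev <- detect_events(tr, params)
  mask <- exclusion_mask(tr, ev$saccades, ev$blinks, pad_ms = cfg$pursuit_pad_ms)
  g <- instantaneous_gain(tr, trial, mask, min_target_speed = cfg$min_target_speed,
                          smooth_window = cfg$gain_smooth_window)
  tg <- trim_gain(g, lo = cfg$gain_trim_lo, hi = cfg$gain_trim_hi)
  list(trial_id = trial$trial_id,
       axis = trial$pursuit_axis,
       gain_samples = tg$retained,
       mean_gain = if (length(tg$retained)) mean(tg$retained) else NA_real_,
       n_saccades = count_pursuit_saccades(ev$saccades),
       excluded_fraction = mean(!mask))
}
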