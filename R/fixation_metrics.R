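# Fixation-stability metrics: square-wave jerks, large intrusive saccades,
# longest period of fixation.

#' Count square-wave jerks in one trial
#'
#' A square-wave jerk (SWJ) is a saccade of < 2 deg amplitude taking gaze
#' away from the target, followed within 300 ms by a second saccade of
#' similar amplitude (difference < 0.75 deg) taking gaze back towards the
#' target. "Away" and "towards" are operationalised by comparing start- and
#' end-point distance to the target. Pairing is greedy left-to-right and
#' each saccade participates in at most one SWJ, so rapid oscillations are
#' not double counted. The 300 ms interval is measured from the offset of
#' the first saccade to the onset of the second by default
#' (`interval_anchor = "onset_onset"` measures onset to onset).
#'
#' @param saccades a [saccade_events()] table, ordered by onset.
#' @param target_xy numeric length-2, target position in degrees.
#' @param max_amplitude,max_interval_ms,max_amp_diff rule constants
#'   (defaults 2 deg, 300 ms, 0.75 deg, all strict).
#' @param interval_anchor `"offset_onset"` or `"onset_onset"`.
#' @return list with `count` and `pairs` (data.frame of first/second row
#'   indices, inter-saccade interval and amplitude difference).
#' @export
count_square_wave_jerks <- function(saccades, target_xy,
                                    max_amplitude = 2,
                                    max_interval_ms = 300,
                                    max_amp_diff = 0.75,
                                    interval_anchor = c("offset_onset", "onset_onset")) {
  interval_anchor <- match.arg(interval_anchor)
  n <- nrow(saccades)
  empty <- data.frame(first = integer(0), second = integer(0),
                      inter_saccade_interval_ms = numeric(0),
                      amplitude_difference_deg = numeric(0))
  if (n < 2L) return(list(count = 0L, pairs = empty))
  s <- as.data.frame(saccades)
  if (is.unsorted(s$onset_ms)) stop("saccades must be ordered by onset")
  d_start <- sqrt((s$start_x - target_xy[1L])^2 + (s$start_y - target_xy[2L])^2)
  d_end <- sqrt((s$end_x - target_xy[1L])^2 + (s$end_y - target_xy[2L])^2)
  away <- d_end > d_start
  toward <- d_end < d_start
  small <- s$amplitude < max_amplitude
  used <- rep(FALSE, n)
  pairs <- empty
  for (i in seq_len(n - 1L)) {
    if (used[i] || !small[i] || !away[i]) next
    anchor <- if (interval_anchor == "offset_onset") s$offset_ms[i] else s$onset_ms[i]
    for (j in (i + 1L):n) {
      if (used[j]) next
      gap <- s$onset_ms[j] - anchor
      if (gap >= max_interval_ms) break
      if (gap < 0) next
      if (!small[j] || !toward[j]) next
      if (abs(s$amplitude[j] - s$amplitude[i]) >= max_amp_diff) next
      used[i] <- used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        first = i, second = j,
        inter_saccade_interval_ms = gap,
        amplitude_difference_deg = abs(s$amplitude[j] - s$amplitude[i])))
      break
    }
  }
  list(count = nrow(pairs), pairs = pairs)
}

#' Count large intrusive saccades
#'
#' Saccades containing a blink are removed; the remainder with amplitude
#' strictly greater than `min_amplitude` (2 deg) are counted.
#'
#' @param saccades a [saccade_events()] table.
#' @param min_amplitude threshold in degrees, strict.
#' @return integer count.
#' @export
count_large_intrusive_saccades <- function(saccades, min_amplitude = 2) {
  s <- as.data.frame(saccades)
  sum(!s$contains_blink & s$amplitude > min_amplitude)
}

#' Longest period of fixation over scored trials
#'
#' The maximum length of time between saccades across all scored trials
#' (practice trials are excluded upstream). Trial boundaries cap intervals:
#' the gap before the first and after the last saccade of a trial counts,
#' bounded by the trial span.
#'
#' @param trials list; each element is a list with `span` (c(start, end) ms)
#'   and `saccades` (a [saccade_events()] table for that trial).
#' @return longest inter-saccade interval in ms.
#' @export
longest_fixation_period <- function(trials) {
  if (!length(trials)) stop("longest_fixation_period: no trials supplied")
  per_trial <- vapply(trials, function(tl) {
    s <- as.data.frame(tl$saccades)
    if (nrow(s) == 0L) return(tl$span[2L] - tl$span[1L])
    iv <- complement_intervals(as.matrix(s[, c("onset_ms", "offset_ms")]),
                               tl$span[1L], tl$span[2L])
    if (nrow(iv) == 0L) return(0)
    max(iv[, 2L] - iv[, 1L])
  }, numeric(1L))
  max(per_trial)
}
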