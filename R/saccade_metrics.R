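# Saccade-task metrics: time to first target fixation, main-saccade
# selection, latency, amplitude error, velocity, saccade counts, removal
# rate and the gap/overlap contrast.

#' Time from target onset to the first fixation upon the target
#'
#' Onset of the earliest fixation whose mean position lies within
#' `window_deg` (2.5 deg) of the target, minus the target onset. A
#' qualifying fixation already ongoing at target onset yields 0 (clamped).
#' `NA` when no qualifying fixation starts within the response window.
#'
#' @param trial one trial record (list or one-row data.frame) with
#'   `target_x`, `target_y`, `target_onset_ms`.
#' @param fixations a [fixation_events()] table for the trial.
#' @param window_deg acceptance radius, degrees.
#' @param response_window_ms latest accepted fixation onset relative to
#'   target onset (5000 ms).
#' @return time in ms, or `NA_real_`.
#' @export
time_to_first_target_fixation <- function(trial, fixations, window_deg = 2.5,
                                          response_window_ms = 5000) {
  f <- as.data.frame(fixations)
  if (nrow(f) == 0L) return(NA_real_)
  d <- sqrt((f$mean_x - trial$target_x)^2 + (f$mean_y - trial$target_y)^2)
  ok <- !is.na(d) & d <= window_deg & f$offset_ms > trial$target_onset_ms &
    f$onset_ms <= trial$target_onset_ms + response_window_ms
  if (!any(ok)) return(NA_real_)
  max(0, min(f$onset_ms[ok]) - trial$target_onset_ms)
}

#' Identify the first major saccade towards the target
#'
#' Removal rules, applied as independent predicates: a saccade is removed if
#' it (1) contains a blink, (2) starts before the target appears, (3) starts
#' more than 2.5 deg from the central fixation point, or (4) is in the wrong
#' direction (angle between its displacement vector and the
#' centre-to-target vector exceeding 45 deg). The first surviving saccade is
#' selected; if its within-trial ordinal is 6 or later the trial is
#' discarded; with no survivor the trial has no candidate. Ordinals count
#' all parsed saccades from trial start, including ones removed by filters.
#'
#' @param trial trial record with `target_x`, `target_y`,
#'   `target_onset_ms`, `eccentricity`.
#' @param saccades a [saccade_events()] table with ordinals.
#' @param start_max_deg max start distance from centre (2.5).
#' @param direction_max_deg max direction error (45).
#' @param max_ordinal last acceptable ordinal (5).
#' @return list: `status` (`"selected"`, `"discarded"`, `"no_candidate"`),
#'   `saccade` (one-row data.frame or `NULL`), `latency_ms`,
#'   `amplitude_error_deg` (signed, positive = overshoot), `peak_velocity`.
#' @export
identify_main_saccade <- function(trial, saccades, start_max_deg = 2.5,
                                  direction_max_deg = 45, max_ordinal = 5) {
  s <- as.data.frame(saccades)
  out <- function(status, row = NULL) {
    list(trial_id = trial$trial_id, status = status, saccade = row,
         latency_ms = if (is.null(row)) NA_real_ else row$onset_ms - trial$target_onset_ms,
         amplitude_error_deg = if (is.null(row)) NA_real_ else row$amplitude - trial$eccentricity,
         peak_velocity = if (is.null(row)) NA_real_ else row$peak_velocity)
  }
  if (nrow(s) == 0L) return(out("no_candidate"))
  tgt <- c(trial$target_x, trial$target_y)
  keep <- !s$contains_blink &
    s$onset_ms >= trial$target_onset_ms &
    sqrt(s$start_x^2 + s$start_y^2) <= start_max_deg &
    direction_error_deg(s$end_x - s$start_x, s$end_y - s$start_y,
                        tgt[1L], tgt[2L]) <= direction_max_deg
  if (!any(keep)) return(out("no_candidate"))
  first <- which(keep)[1L]
  if (s$ordinal[first] > max_ordinal) return(out("discarded"))
  out("selected", s[first, , drop = FALSE])
}

#' Angle in degrees between a displacement vector and the reference
#' centre-to-target vector
#' @keywords internal
direction_error_deg <- function(dx, dy, tx, ty) {
  dn <- sqrt(dx^2 + dy^2) * sqrt(tx^2 + ty^2)
  cosang <- (dx * tx + dy * ty) / dn
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ang[dn == 0] <- 180
  ang
}

#' Latency of the main saccade
#'
#' @param result output of [identify_main_saccade()].
#' @return onset minus target onset in ms; `NA` unless status is selected.
#' @export
saccade_latency <- function(result) {
  if (!identical(result$status, "selected")) return(NA_real_)
  result$latency_ms
}

#' Signed amplitude error of the main saccade
#'
#' Amplitude minus target eccentricity: positive = overshoot (hypermetria),
#' negative = undershoot (hypometria).
#'
#' @param result output of [identify_main_saccade()].
#' @param trial the trial record (used when the result lacks the error).
#' @return degrees, or `NA` unless selected.
#' @export
amplitude_error <- function(result, trial = NULL) {
  if (!identical(result$status, "selected")) return(NA_real_)
  if (!is.null(trial)) result$saccade$amplitude - trial$eccentricity
  else result$amplitude_error_deg
}

#' Square-root transform with per-group +/- 2 SD trim
#'
#' Values are square-root transformed; within each group, entries further
#' than `z_max` sample standard deviations (n-1 denominator) from that
#' group's transformed mean are removed. Groups with fewer than 3
#' observations, or zero SD, are passed through untrimmed (with a warning
#' for small groups).
#'
#' @param values non-negative numeric vector (`NA` allowed; never retained).
#' @param groups group label per value.
#' @param z_max trim threshold in SD units (default 2, strict).
#' @return list: `transformed` (sqrt values), `keep` (logical retention
#'   mask) and `retained` (kept transformed values).
#' @export
sqrt_transform_trim <- function(values, groups, z_max = 2) {
  if (any(values < 0, na.rm = TRUE)) stop("sqrt_transform_trim: negative values")
  tv <- sqrt(values)
  keep <- !is.na(tv)
  for (g in unique(groups)) {
    sel <- which(groups == g & keep)
    if (length(sel) < 3L) {
      if (length(sel) > 0L) warning("group ", g, " has < 3 observations; trim skipped")
      next
    }
    m <- mean(tv[sel]); s <- stats::sd(tv[sel])
    if (!is.finite(s) || s == 0) next
    keep[sel] <- abs(tv[sel] - m) <= z_max * s
  }
  list(transformed = tv, keep = keep, retained = tv[keep])
}

#' Count saccades made after target onset
#'
#' Saccades with onset at or after target onset, not containing a blink,
#' with amplitude strictly greater than 2 deg.
#'
#' @param trial trial record with `target_onset_ms`.
#' @param saccades a [saccade_events()] table.
#' @param min_amplitude threshold in degrees, strict.
#' @return integer count.
#' @export
count_trial_saccades <- function(trial, saccades, min_amplitude = 2) {
  s <- as.data.frame(saccades)
  sum(s$onset_ms >= trial$target_onset_ms & !s$contains_blink &
        s$amplitude > min_amplitude)
}

#' Proportion of trials removed by the main-saccade algorithm
#'
#' @param results list of [identify_main_saccade()] outputs.
#' @return (discarded + no_candidate) / total.
#' @export
removal_rate <- function(results) {
  st <- vapply(results, `[[`, "", "status")
  mean(st != "selected")
}

#' Per-group overlap minus gap contrast
#'
#' Per participant, the mean difference (overlap - gap) of a timing metric,
#' optionally on the square-root scale used for analysis; then group
#' summaries. Participants missing one condition are excluded with a
#' warning.
#'
#' @param rows data.frame with `participant_id`, `group`, `condition`
#'   (`"gap"`/`"overlap"`) and `value`.
#' @param transform `"none"` or `"sqrt"`.
#' @return list: `per_participant` (data.frame with `contrast`) and
#'   `by_group` (data.frame with mean contrast, SD, n).
#' @export
gap_overlap_effect <- function(rows, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  v <- rows$value
  if (transform == "sqrt") v <- sqrt(v)
  rows$v <- v
  per <- lapply(split(rows, rows$participant_id), function(d) {
    mo <- mean(d$v[d$condition == "overlap"], na.rm = TRUE)
    mg <- mean(d$v[d$condition == "gap"], na.rm = TRUE)
    if (!is.finite(mo) || !is.finite(mg)) {
      warning("participant ", d$participant_id[1L],
              " missing a condition; excluded from gap/overlap contrast")
      return(NULL)
    }
    data.frame(participant_id = d$participant_id[1L], group = d$group[1L],
               contrast = mo - mg)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no participant with both conditions")
  by_group <- do.call(rbind, lapply(split(per, per$group), function(d) {
    data.frame(group = d$group[1L], mean_contrast = mean(d$contrast),
               sd_contrast = stats::sd(d$contrast), n = nrow(d))
  }))
  rownames(by_group) <- NULL
  list(per_participant = per, by_group = by_group)
}
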