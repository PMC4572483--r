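# Event detection: velocity/acceleration threshold parsing of gaze traces
# into saccades, fixations and blink spans.

#' Per-sample gaze kinematics
#'
#' Speed is the Euclidean norm of the central-difference velocity of (x, y);
#' acceleration is the central difference of speed. Endpoints use one-sided
#' differences. Samples whose difference stencil touches an invalid sample
#' get `NA`. An optional moving-average pre-smoother (`smooth_window = 3`)
#' is available; the default differentiates the raw 250 Hz signal.
#'
#' @param tr a [gaze_trace()].
#' @param smooth_window odd integer; 1 disables smoothing.
#' @return list with `vx`, `vy`, `speed` (deg/s) and `accel` (deg/s^2),
#'   each of trace length.
#' @export
estimate_kinematics <- function(tr, smooth_window = 1) {
  validate_gaze_trace(tr)
  n <- length(tr$t)
  if (!any(tr$valid)) {
    warning("all samples invalid; kinematics undefined")
    na <- rep(NA_real_, n)
    return(list(vx = na, vy = na, speed = na, accel = na))
  }
  x <- tr$x; y <- tr$y; valid <- tr$valid
  if (smooth_window > 1L) {
    k <- as.integer(smooth_window)
    x <- stats::filter(x, rep(1 / k, k), sides = 2)
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
    x <- as.numeric(x); y <- as.numeric(y)
    # endpoints fall back to the raw samples
    x[is.na(x)] <- tr$x[is.na(x)]; y[is.na(y)] <- tr$y[is.na(y)]
  }
  ts <- tr$t / 1000  # seconds
  d_central <- function(z) {
    out <- rep(NA_real_, n)
    out[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (ts[3:n] - ts[1:(n - 2)])
    out[1L] <- (z[2L] - z[1L]) / (ts[2L] - ts[1L])
    out[n] <- (z[n] - z[n - 1L]) / (ts[n] - ts[n - 1L])
    out
  }
  vx <- d_central(x); vy <- d_central(y)
  # a sample's stencil touches its neighbours; invalidate accordingly
  vok <- valid
  vok[2:(n - 1)] <- valid[2:(n - 1)] & valid[1:(n - 2)] & valid[3:n]
  vok[1L] <- valid[1L] & valid[2L]
  vok[n] <- valid[n] & valid[n - 1L]
  vx[!vok] <- NA_real_; vy[!vok] <- NA_real_
  speed <- sqrt(vx^2 + vy^2)
  sp0 <- speed; sp0[is.na(sp0)] <- 0  # acceleration stencil handled via vok below
  accel <- d_central(ifelse(is.na(speed), 0, speed))
  aok <- vok
  aok[2:(n - 1)] <- vok[2:(n - 1)] & vok[1:(n - 2)] & vok[3:n]
  aok[1L] <- vok[1L] & vok[2L]; aok[n] <- vok[n] & vok[n - 1L]
  accel[!aok] <- NA_real_
  list(vx = vx, vy = vy, speed = speed, accel = accel)
}

#' Detect blink / pupil-loss spans
#'
#' Maximal runs of `valid = FALSE`, each padded by `pad_ms` on both sides,
#' merged where padded spans overlap and clipped to the trace span.
#'
#' @param tr a [gaze_trace()].
#' @param pad_ms padding in ms (default 50).
#' @return data.frame with columns `trial_id`, `onset_ms`, `offset_ms`
#'   (zero rows when the trace is fully valid).
#' @export
detect_blinks <- function(tr, pad_ms = 50) {
  r <- rle(!tr$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  if (!length(idx)) {
    return(data.frame(trial_id = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0)))
  }
  iv <- cbind(tr$t[starts[idx]] - pad_ms, tr$t[ends[idx]] + pad_ms)
  iv <- merge_intervals(clip_intervals(iv, tr$t[1L], tr$t[length(tr$t)]))
  data.frame(trial_id = rep(as.character(tr$trial_id), nrow(iv)),
             onset_ms = iv[, 1L], offset_ms = iv[, 2L])
}

#' Detect saccades by velocity/acceleration thresholds
#'
#' A saccade is a maximal run of samples with speed above
#' `velocity_threshold` or |acceleration| above `acceleration_threshold`,
#' lasting at least `min_saccade_duration_ms`. Runs separated only by an
#' invalid (blink) gap are merged into a single event; events overlapping a
#' padded blink span are flagged `contains_blink` rather than dropped,
#' because several downstream metrics exclude blink-contaminated saccades
#' explicitly.
#'
#' @param tr a [gaze_trace()].
#' @param params a [parser_params()] list.
#' @return a [saccade_events()] table ordered by onset, with 1-based
#'   `ordinal` within the trial.
#' @export
detect_saccades <- function(tr, params = parser_params()) {
  kin <- estimate_kinematics(tr, smooth_window = params$smooth_window)
  n <- length(tr$t)
  blinks <- detect_blinks(tr, params$blink_pad_ms)
  biv <- as_interval_matrix(blinks[, c("onset_ms", "offset_ms")])
  hit <- (kin$speed > params$velocity_threshold) |
    (abs(kin$accel) > params$acceleration_threshold)
  hit[is.na(hit)] <- FALSE
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  if (!length(idx)) return(saccade_events())
  runs <- cbind(starts[idx], ends[idx])
  # merge candidate runs bridged by an invalid gap (a blink mid-saccade)
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- seq(merged[nrow(merged), 2L] + 1L, runs[i, 1L] - 1L)
      if (length(gap) && all(is.na(kin$speed[gap]))) {
        merged[nrow(merged), 2L] <- runs[i, 2L]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  # boundary position: short window mean just outside the threshold run, so
  # the sub-threshold tails of the velocity profile are not clipped off the
  # amplitude (and sample noise is averaged down)
  edge_pos <- function(i, side) {
    # skip ~20 ms of sub-threshold velocity tail, then average ~24 ms
    w <- if (side == "pre") seq(i - 11L, i - 6L) else seq(i + 6L, i + 11L)
    w <- w[w >= 1L & w <= n]
    w <- w[tr$valid[w]]
    if (!length(w)) {
      i0 <- i
      if (side == "pre") while (i0 > 1L && !tr$valid[i0]) i0 <- i0 - 1L
      else while (i0 < n && !tr$valid[i0]) i0 <- i0 + 1L
      if (!tr$valid[i0]) return(NULL)
      w <- i0
    }
    c(mean(tr$x[w]), mean(tr$y[w]))
  }
  evs <- lapply(seq_len(nrow(runs)), function(k) {
    i <- runs[k, 1L]; j <- runs[k, 2L]
    if (tr$t[j] - tr$t[i] < params$min_saccade_duration_ms) return(NULL)
    p0 <- edge_pos(i, "pre"); p1 <- edge_pos(j, "post")
    if (is.null(p0) || is.null(p1)) return(NULL)
    data.frame(trial_id = as.character(tr$trial_id),
               onset_ms = tr$t[i], offset_ms = tr$t[j],
               start_x = p0[1L], start_y = p0[2L],
               end_x = p1[1L], end_y = p1[2L],
               amplitude = sqrt(sum((p1 - p0)^2)),
               peak_velocity = suppressWarnings(max(kin$speed[i:j], na.rm = TRUE)),
               contains_blink = FALSE)
  })
  evs <- do.call(rbind, evs)
  if (is.null(evs) || nrow(evs) == 0L) return(saccade_events())
  evs$peak_velocity[!is.finite(evs$peak_velocity)] <- NA_real_
  evs$contains_blink <- intervals_overlap_any(
    evs[, c("onset_ms", "offset_ms")], biv)
  evs <- evs[order(evs$onset_ms), , drop = FALSE]
  evs$ordinal <- seq_len(nrow(evs))
  do.call(saccade_events, evs)
}

#' Detect fixations as the complement of saccades and blinks
#'
#' Fixations are the maximal sub-intervals of the trial not covered by a
#' saccade or padded blink span, kept when at least
#' `min_fixation_duration_ms` long; shorter gaps are returned as residue so
#' the events tile the trace exactly.
#'
#' @param tr a [gaze_trace()].
#' @param saccades a [saccade_events()] table for this trial.
#' @param blinks data.frame from [detect_blinks()].
#' @param params a [parser_params()] list.
#' @return list with `fixations` (a [fixation_events()] table) and
#'   `residue` (interval matrix of sub-minimum gaps).
#' @export
detect_fixations <- function(tr, saccades, blinks, params = parser_params()) {
  span <- trace_span(tr)
  occupied <- rbind(as_interval_matrix(saccades[, c("onset_ms", "offset_ms")]),
                    as_interval_matrix(blinks[, c("onset_ms", "offset_ms")]))
  free <- complement_intervals(occupied, span[1L], span[2L])
  keep <- (free[, 2L] - free[, 1L]) >= params$min_fixation_duration_ms
  residue <- free[!keep, , drop = FALSE]
  free <- free[keep, , drop = FALSE]
  if (nrow(free) == 0L) {
    return(list(fixations = fixation_events(), residue = residue))
  }
  rows <- lapply(seq_len(nrow(free)), function(k) {
    sel <- tr$t >= free[k, 1L] & tr$t <= free[k, 2L] & tr$valid
    data.frame(trial_id = as.character(tr$trial_id),
               onset_ms = free[k, 1L], offset_ms = free[k, 2L],
               mean_x = if (any(sel)) mean(tr$x[sel]) else NA_real_,
               mean_y = if (any(sel)) mean(tr$y[sel]) else NA_real_,
               duration_ms = free[k, 2L] - free[k, 1L])
  })
  list(fixations = do.call(fixation_events, do.call(rbind, rows)),
       residue = residue)
}

#' Full event detection for one trace
#'
#' @param tr a [gaze_trace()].
#' @param params a [parser_params()] list.
#' @return list with `saccades`, `fixations`, `blinks`, `residue`.
#' @export
detect_events <- function(tr, params = parser_params()) {
  blinks <- detect_blinks(tr, params$blink_pad_ms)
  saccades <- detect_saccades(tr, params)
  fx <- detect_fixations(tr, saccades, blinks, params)
  list(saccades = saccades, fixations = fx$fixations, blinks = blinks,
       residue = fx$residue)
}
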