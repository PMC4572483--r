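# Synthetic gaze-trace simulator: task schedules and 250 Hz traces with
# known ground truth, emulating the statistical structure the analysis
# pipeline assumes (main-sequence saccades, blinks, group-dependent
# latency/amplitude/gain phenotypes).

#' Cohort profile: a synthetic group's oculomotor phenotype
#'
#' @param group_label group name (e.g. "control", "tAD", "PCA").
#' @param n_participants number of participants to simulate.
#' @param age_mean,age_sd age distribution, years.
#' @param swj_rate expected square-wave jerks per 10 s fixation trial.
#' @param intrusion_rate expected large (> 2 deg) intrusion episodes per
#'   fixation trial (each episode = outgoing + return saccade).
#' @param latency_median_ms,latency_sigma log-normal main-saccade latency
#'   (median in ms; sigma on the log scale).
#' @param overlap_penalty_ms additive latency cost in overlap trials.
#' @param saccadic_gain expected main-saccade amplitude / eccentricity.
#' @param velocity_scale multiplier on main-sequence peak velocity.
#' @param pursuit_gain_h,pursuit_gain_v smooth-pursuit velocity gain per axis.
#' @param catchup_rate expected extra (anticipatory) pursuit saccades per
#'   trial, on top of error-triggered catch-ups.
#' @param blink_rate expected blinks per trial.
#' @param noise_sd_deg positional noise SD (band-limited; see vignette).
#' @param pseudo_score_loading correlation of simulated neuropsychological
#'   pseudo-scores with the participant's true latency.
#' @param wrong_dir_prob probability the first target-directed saccade goes
#'   in the wrong direction.
#' @param pretarget_rate expected task-irrelevant saccades before target
#'   onset per saccade trial (fixation impersistence).
#' @return list of class `cohort_profile`.
#' @export
cohort_profile <- function(group_label, n_participants = 10,
                           age_mean = 65, age_sd = 7,
                           swj_rate = 1.5, intrusion_rate = 0.3,
                           latency_median_ms = 220, latency_sigma = 0.25,
                           overlap_penalty_ms = 30,
                           saccadic_gain = 0.95, velocity_scale = 1,
                           pursuit_gain_h = 0.9, pursuit_gain_v = 0.67,
                           catchup_rate = 1, blink_rate = 0.3,
                           noise_sd_deg = 0.1, pseudo_score_loading = 0.6,
                           wrong_dir_prob = 0.02, pretarget_rate = 0.05) {
  p <- as.list(environment())
  stopifnot(p$n_participants >= 1,
            p$swj_rate >= 0, p$intrusion_rate >= 0, p$catchup_rate >= 0,
            p$blink_rate >= 0, p$pretarget_rate >= 0,
            p$latency_sigma > 0, p$latency_median_ms > 0,
            p$saccadic_gain > 0, p$saccadic_gain <= 1.5,
            p$pursuit_gain_h > 0, p$pursuit_gain_h <= 1.5,
            p$pursuit_gain_v > 0, p$pursuit_gain_v <= 1.5,
            p$noise_sd_deg >= 0,
            p$wrong_dir_prob >= 0, p$wrong_dir_prob <= 1)
  class(p) <- "cohort_profile"
  p
}

#' Default group profiles
#'
#' Calibrated only to reproduce the qualitative group ordering observed
#' clinically (PCA slow, hypometric, overlap-sensitive; typical Alzheimer's
#' disease frequent square-wave jerks and elevated velocity; both patient
#' groups sub-control pursuit gain), never exact cohort values.
#'
#' @param n_control,n_tad,n_pca group sizes.
#' @return named list of three [cohort_profile()]s.
#' @export
default_profiles <- function(n_control = 22, n_tad = 17, n_pca = 20) {
  list(
    control = cohort_profile("control", n_control, age_mean = 63.3, age_sd = 6.2,
                             swj_rate = 1.2, intrusion_rate = 0.3,
                             latency_median_ms = 220, latency_sigma = 0.22,
                             overlap_penalty_ms = 30, saccadic_gain = 0.95,
                             velocity_scale = 1.0, pursuit_gain_h = 0.90,
                             pursuit_gain_v = 0.67, catchup_rate = 1,
                             blink_rate = 0.3, wrong_dir_prob = 0.02,
                             pretarget_rate = 0.05, pseudo_score_loading = 0.6),
    tAD = cohort_profile("tAD", n_tad, age_mean = 67.4, age_sd = 5.9,
                         swj_rate = 4.0, intrusion_rate = 0.6,
                         latency_median_ms = 245, latency_sigma = 0.26,
                         overlap_penalty_ms = 40, saccadic_gain = 0.92,
                         velocity_scale = 1.15, pursuit_gain_h = 0.78,
                         pursuit_gain_v = 0.55, catchup_rate = 3,
                         blink_rate = 0.4, wrong_dir_prob = 0.04,
                         pretarget_rate = 0.15, pseudo_score_loading = 0.6),
    PCA = cohort_profile("PCA", n_pca, age_mean = 63.2, age_sd = 8.9,
                         swj_rate = 1.5, intrusion_rate = 1.2,
                         latency_median_ms = 320, latency_sigma = 0.35,
                         overlap_penalty_ms = 120, saccadic_gain = 0.72,
                         velocity_scale = 1.0, pursuit_gain_h = 0.70,
                         pursuit_gain_v = 0.47, catchup_rate = 4,
                         blink_rate = 0.5, wrong_dir_prob = 0.10,
                         pretarget_rate = 0.4, pseudo_score_loading = 0.8)
  )
}

#' Main-sequence peak velocity
#'
#' V = eta * scale * (1 - exp(-A / c)) with eta = 500 deg/s, c = 14 deg
#' (literature-typical constants, configurable).
#'
#' @param amplitude saccade amplitude, deg.
#' @param velocity_scale multiplier.
#' @param eta,c main-sequence constants.
#' @return peak velocity, deg/s.
#' @export
main_sequence_peak <- function(amplitude, velocity_scale = 1, eta = 500, c = 14) {
  eta * velocity_scale * (1 - exp(-amplitude / c))
}

#' Simulated saccade displacement waveform
#'
#' A raised-cosine velocity profile: velocity
#' `v(tau) = (Vp/2) * (1 - cos(2*pi*tau/D))` with peak `Vp` from the main
#' sequence, duration `D = 2A/Vp` so the integrated displacement equals the
#' amplitude exactly. Sampled at the trace rate.
#'
#' @param amplitude amplitude A, deg (> 0).
#' @param velocity_scale main-sequence multiplier.
#' @param rate_hz sampling rate.
#' @return data.frame with `t_ms` (from onset) and `s` (displacement along
#'   the saccade direction, deg); attributes `peak_velocity` and
#'   `duration_ms`.
#' @export
simulate_saccade_waveform <- function(amplitude, velocity_scale = 1,
                                      rate_hz = 250) {
  stopifnot(amplitude > 0)
  vp <- main_sequence_peak(amplitude, velocity_scale)
  dur <- 2 * amplitude / vp * 1000  # ms
  t <- seq(0, dur, by = 1000 / rate_hz)
  tau <- t / dur
  s <- amplitude * (tau - sin(2 * pi * tau) / (2 * pi))
  out <- data.frame(t_ms = t, s = s)
  attr(out, "peak_velocity") <- vp
  attr(out, "duration_ms") <- dur
  out
}

#' Band-limited positional noise
#'
#' Moving-average filtered white noise rescaled to the requested SD; a
#' window of 1 reproduces white noise.
#' @keywords internal
simulate_noise <- function(n, sd, window = 25L) {
  if (sd == 0) return(numeric(n))
  if (window <= 1L) return(stats::rnorm(n, 0, sd))
  e <- stats::rnorm(n + 2L * window, 0, sd * sqrt(window))
  y <- stats::filter(e, rep(1 / window, window), sides = 2)
  as.numeric(y)[window + seq_len(n)]
}

# Displacement profile evaluated on the sample grid; adds a saccade with
# vector displacement (dx, dy) starting at sample index i0 to the offset
# arrays. Returns the updated arrays and the end index.
add_saccade_to <- function(ox, oy, t, i0, dx, dy, velocity_scale, rate_hz) {
  A <- sqrt(dx^2 + dy^2)
  if (A <= 0) return(list(ox = ox, oy = oy, end = i0, duration_ms = 0))
  wf <- simulate_saccade_waveform(A, velocity_scale, rate_hz)
  nseg <- nrow(wf)
  n <- length(t)
  idx <- i0 + seq_len(nseg) - 1L
  idx <- idx[idx <= n]
  frac <- wf$s[seq_along(idx)] / A
  ox[idx] <- ox[idx] + dx * frac
  oy[idx] <- oy[idx] + dy * frac
  if (max(idx) < n) {
    rest <- (max(idx) + 1L):n
    ox[rest] <- ox[rest] + dx
    oy[rest] <- oy[rest] + dy
  }
  list(ox = ox, oy = oy, end = max(idx), duration_ms = attr(wf, "duration_ms"))
}

# Draw a free onset (ms) at least `sep` away from occupied intervals.
draw_free_time <- function(lo, hi, occupied, sep = 400, tries = 60L) {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NA_real_)
  for (k in seq_len(tries)) {
    cand <- stats::runif(1, lo, hi)
    if (nrow(occupied) == 0L ||
        !any(cand + sep > occupied[, 1L] & cand - sep < occupied[, 2L])) {
      return(cand)
    }
  }
  NA_real_
}

#' Simulate one fixation-stability trial
#'
#' Gaze rests on the target with band-limited noise; a Poisson number of
#' square-wave jerks (paired sub-2 deg out/return saccades, return within
#' 300 ms, amplitude difference < 0.75 deg) and of large intrusion episodes
#' (> 2 deg out, delayed return) are injected, plus optional blinks.
#'
#' @param profile a [cohort_profile()].
#' @param target_xy target position (deg), default centre.
#' @param trial_id identifier.
#' @param duration_s trial duration (10 s).
#' @param seed optional integer seed.
#' @param rate_hz sampling rate.
#' @return list: `trace` (a [gaze_trace()]) and `truth` (injected events).
#' @export
simulate_fixation_trial <- function(profile, target_xy = c(0, 0),
                                    trial_id = "fix1", duration_s = 10,
                                    seed = NULL, rate_hz = 250) {
  if (!is.null(seed)) set.seed(seed)
  step <- 1000 / rate_hz
  t <- seq(0, duration_s * 1000 - step, by = step)
  n <- length(t)
  ox <- rep(0, n); oy <- rep(0, n)  # offsets from target
  truth <- list()
  occupied <- matrix(numeric(0), ncol = 2L)
  n_swj <- stats::rpois(1L, profile$swj_rate)
  n_intr <- stats::rpois(1L, profile$intrusion_rate)
  n_blink <- stats::rpois(1L, profile$blink_rate)
  cur <- c(0, 0)  # quasi-static offset between episodes (kept near zero)
  add_episode <- function(kind) {
    span_need <- if (kind == "swj") 600 else 1500
    on <- draw_free_time(400, duration_s * 1000 - span_need - 400, occupied,
                         sep = 450)
    if (is.na(on)) return(NULL)
    i0 <- findInterval(on, t)
    th <- stats::runif(1, 0, 2 * pi)
    # SWJ amplitudes live in [1.25, 1.7] deg: the lower edge keeps the return
    # saccade above the ~1 deg detection floor implied by the 30 deg/s
    # threshold and the main sequence; the upper edge keeps measured
    # amplitudes (noise SD ~0.13) clear of the strict < 2 deg rule gate
    amp <- if (kind == "swj") stats::runif(1, 1.25, 1.7) else stats::runif(1, 2.5, 5)
    dx <- amp * cos(th); dy <- amp * sin(th)
    r1 <- add_saccade_to(ox, oy, t, i0, dx, dy, profile$velocity_scale, rate_hz)
    ox <<- r1$ox; oy <<- r1$oy
    # return saccade: straight back towards the target, landing within 0.3 deg
    land <- c(ox[r1$end], oy[r1$end])
    dback <- sqrt(sum(land^2))
    eps <- stats::runif(1, -0.25, 0.25)
    ret_amp <- dback - eps
    if (kind == "swj") ret_amp <- min(max(ret_amp, 1.05), 1.9)  # both < 2 deg, detectable
    gap_ms <- if (kind == "swj") stats::runif(1, 100, 230) else stats::runif(1, 400, 900)
    j0 <- findInterval(t[r1$end] + gap_ms, t)
    udir <- -land / dback
    r2 <- add_saccade_to(ox, oy, t, j0, udir[1L] * ret_amp, udir[2L] * ret_amp,
                         profile$velocity_scale, rate_hz)
    ox <<- r2$ox; oy <<- r2$oy
    occupied <<- rbind(occupied, c(on, t[r2$end]))
    truth[[length(truth) + 1L]] <<- data.frame(
      type = paste0(kind, c("_out", "_return")),
      onset_ms = c(t[i0], t[j0]), amplitude = c(amp, abs(ret_amp)))
    invisible(NULL)
  }
  for (k in seq_len(n_swj)) add_episode("swj")
  for (k in seq_len(n_intr)) add_episode("intrusion")
  x <- target_xy[1L] + ox + simulate_noise(n, profile$noise_sd_deg)
  y <- target_xy[2L] + oy + simulate_noise(n, profile$noise_sd_deg)
  valid <- rep(TRUE, n)
  blink_spans <- list()
  for (k in seq_len(n_blink)) {
    on <- stats::runif(1, 200, duration_s * 1000 - 600)
    len <- stats::runif(1, 120, 260)
    sel <- t >= on & t <= on + len
    valid[sel] <- FALSE
    blink_spans[[k]] <- c(on, on + len)
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), onset_ms = numeric(0), amplitude = numeric(0))
  list(trace = gaze_trace(trial_id, t, x, y, valid, rate_hz),
       truth = list(events = truth_df, n_swj_injected = sum(truth_df$type == "swj_out"),
                    n_intrusions_injected = sum(truth_df$type == "intrusion_out"),
                    blinks = blink_spans))
}

#' Simulate one gap/overlap saccade trial
#'
#' Gaze holds the centre, the main saccade launches after a log-normal
#' latency (plus the overlap penalty in overlap trials) with amplitude
#' `saccadic_gain * eccentricity` plus noise; corrective saccades bridge the
#' residual error until gaze is within 1.5 deg of the target or the 5000 ms
#' response window elapses. With probability `wrong_dir_prob` the first
#' saccade goes in a wrong direction.
#'
#' @param profile a [cohort_profile()].
#' @param trial one saccade trial record (row of [build_task_schedule()]).
#' @param seed optional integer seed.
#' @param rate_hz sampling rate.
#' @param latency_median_ms override of the profile's median (used to give
#'   each participant their own latency level).
#' @return list: `trace` and `truth` (true latency, intended main saccade).
#' @export
simulate_saccade_trial <- function(profile, trial, seed = NULL, rate_hz = 250,
                                   latency_median_ms = NULL) {
  if (!is.null(seed)) set.seed(seed)
  step <- 1000 / rate_hz
  med <- if (is.null(latency_median_ms)) profile$latency_median_ms else latency_median_ms
  lat <- stats::rlnorm(1, log(med), profile$latency_sigma)
  if (identical(trial$condition, "overlap")) lat <- lat + profile$overlap_penalty_ms
  lat <- min(lat, 4000)
  t_end <- trial$target_onset_ms + 5400
  t <- seq(0, t_end, by = step)
  n <- length(t)
  ox <- rep(0, n); oy <- rep(0, n)
  tgt <- c(trial$target_x, trial$target_y)
  truth_events <- list()
  # pre-target impersistence saccades (out and back, small)
  n_pre <- stats::rpois(1L, profile$pretarget_rate)
  for (k in seq_len(n_pre)) {
    on <- stats::runif(1, 80, max(120, trial$target_onset_ms - 150))
    th <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 1.2, 3)
    i0 <- findInterval(on, t)
    r <- add_saccade_to(ox, oy, t, i0, amp * cos(th), amp * sin(th),
                        profile$velocity_scale, rate_hz)
    ox <- r$ox; oy <- r$oy
    truth_events[[length(truth_events) + 1L]] <-
      data.frame(type = "pretarget", onset_ms = t[i0], amplitude = amp)
  }
  cur_time <- trial$target_onset_ms + lat
  wrong <- stats::runif(1) < profile$wrong_dir_prob
  first <- TRUE
  main_onset <- NA_real_; main_amp <- NA_real_
  repeat {
    i0 <- findInterval(cur_time, t)
    if (i0 >= n - 2L) break
    cur <- c(ox[i0], oy[i0])
    to_tgt <- tgt - cur
    dist <- sqrt(sum(to_tgt^2))
    if (dist <= 1.5 && !first) break
    if (first) {
      amp <- max(0.5, profile$saccadic_gain * trial$eccentricity +
                   stats::rnorm(1, 0, 0.3))
      if (wrong) {
        rot <- stats::runif(1, 100, 180) * pi / 180 * sample(c(-1, 1), 1L)
        th0 <- atan2(to_tgt[2L], to_tgt[1L]) + rot
        disp <- amp * c(cos(th0), sin(th0))
      } else {
        disp <- to_tgt / dist * amp
      }
      main_onset <- t[i0]; main_amp <- amp
      truth_events[[length(truth_events) + 1L]] <-
        data.frame(type = if (wrong) "main_wrong" else "main",
                   onset_ms = t[i0], amplitude = amp)
      first <- FALSE
    } else {
      amp <- max(0.3, 0.9 * dist + stats::rnorm(1, 0, 0.15))
      disp <- to_tgt / dist * amp
      truth_events[[length(truth_events) + 1L]] <-
        data.frame(type = "corrective", onset_ms = t[i0], amplitude = amp)
    }
    r <- add_saccade_to(ox, oy, t, i0, disp[1L], disp[2L],
                        profile$velocity_scale, rate_hz)
    ox <- r$ox; oy <- r$oy
    cur_time <- t[r$end] + stats::runif(1, 150, 280)
    if (cur_time > trial$target_onset_ms + 5000) break
  }
  # truncate the trace 600 ms after gaze settles (or at the window end)
  settle <- min(cur_time + 600, t_end)
  keep <- t <= settle
  t <- t[keep]; ox <- ox[keep]; oy <- oy[keep]; n <- length(t)
  x <- ox + simulate_noise(n, profile$noise_sd_deg)
  y <- oy + simulate_noise(n, profile$noise_sd_deg)
  valid <- rep(TRUE, n)
  n_blink <- stats::rpois(1L, profile$blink_rate)
  for (k in seq_len(n_blink)) {
    on <- stats::runif(1, 100, max(200, t[n] - 400))
    len <- stats::runif(1, 120, 260)
    valid[t >= on & t <= on + len] <- FALSE
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  truth_df <- if (length(truth_events)) do.call(rbind, truth_events) else
    data.frame(type = character(0), onset_ms = numeric(0), amplitude = numeric(0))
  list(trace = gaze_trace(trial$trial_id, t, x, y, valid, rate_hz),
       truth = list(events = truth_df, true_latency_ms = lat,
                    main_onset_ms = main_onset, main_amplitude = main_amp,
                    wrong_direction = wrong))
}

#' Simulate one sinusoidal pursuit trial
#'
#' Between saccades the eye moves at `gain` times the target velocity;
#' positional error exceeding 1.5 deg sustained for 60 ms triggers a
#' catch-up saccade, and `catchup_rate` adds Poisson-count anticipatory
#' saccades. Gain is axis-specific.
#'
#' @param profile a [cohort_profile()].
#' @param trial pursuit trial record.
#' @param seed optional integer seed.
#' @param rate_hz sampling rate.
#' @return list: `trace` and `truth` (true gain, catch-up saccades).
#' @export
simulate_pursuit_trial <- function(profile, trial, seed = NULL, rate_hz = 250) {
  if (!is.null(seed)) set.seed(seed)
  step <- 1000 / rate_hz
  dur <- trial$pursuit_duration_s
  if (is.null(dur) || is.na(dur)) dur <- 10
  t <- seq(0, dur * 1000 - step, by = step)
  n <- length(t)
  g <- if (identical(trial$pursuit_axis, "vertical")) profile$pursuit_gain_v
       else profile$pursuit_gain_h
  tk <- target_kinematics(trial, t)
  adj <- rep(0, n)  # saccadic displacement accumulated on the pursuit axis
  truth_events <- list()
  add_jump <- function(i0, disp) {
    r <- add_saccade_to(adj, rep(0, n), t, i0, disp, 0,
                        profile$velocity_scale, rate_hz)
    adj <<- r$ox
    truth_events[[length(truth_events) + 1L]] <<-
      data.frame(type = "catchup", onset_ms = t[i0], amplitude = abs(disp))
    r$end
  }
  # anticipatory extras
  n_extra <- stats::rpois(1L, profile$catchup_rate)
  extra_times <- sort(stats::runif(n_extra, 800, dur * 1000 - 800))
  for (et in extra_times) {
    i0 <- findInterval(et, t)
    err <- tk$pos[i0] - (g * tk$pos[i0] + adj[i0])
    ahead <- sign(tk$vel[i0])
    if (ahead == 0) ahead <- 1
    disp <- err + ahead * stats::runif(1, 2.2, 3.2)
    add_jump(i0, disp)
  }
  # error-triggered catch-ups
  win <- max(1L, round(60 / step))  # sustained-error window, samples
  i <- win + 1L
  while (i <= n - 10L) {
    err <- tk$pos - (g * tk$pos + adj)
    breach <- abs(err) > 1.5
    run <- which(vapply(i:(n - 1L), function(j) {
      all(breach[(j - win + 1L):j])
    }, logical(1L)))
    if (!length(run)) break
    i0 <- i + run[1L] - 1L
    disp <- err[i0] * 0.95 + stats::rnorm(1, 0, 0.1)
    end <- add_jump(i0, disp)
    i <- end + max(1L, round(100 / step))
  }
  pos <- g * tk$pos + adj
  noise_ax <- simulate_noise(n, profile$noise_sd_deg)
  noise_off <- simulate_noise(n, profile$noise_sd_deg)
  if (identical(trial$pursuit_axis, "vertical")) {
    x <- noise_off; y <- pos + noise_ax
  } else {
    x <- pos + noise_ax; y <- noise_off
  }
  valid <- rep(TRUE, n)
  n_blink <- stats::rpois(1L, profile$blink_rate)
  for (k in seq_len(n_blink)) {
    on <- stats::runif(1, 300, dur * 1000 - 600)
    len <- stats::runif(1, 120, 260)
    valid[t >= on & t <= on + len] <- FALSE
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  truth_df <- if (length(truth_events)) do.call(rbind, truth_events) else
    data.frame(type = character(0), onset_ms = numeric(0), amplitude = numeric(0))
  list(trace = gaze_trace(trial$trial_id, t, x, y, valid, rate_hz),
       truth = list(events = truth_df, true_gain = g,
                    axis = trial$pursuit_axis))
}
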