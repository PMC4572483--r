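# Shared fixtures and independent oracles used across the suite.

# A trace sampled at `rate` Hz holding position (x, y) with optional blinks.
static_trace <- function(duration_s = 2, x = 0, y = 0, rate = 250,
                         trial_id = "t1") {
  t <- seq(0, duration_s * 1000 - 1000 / rate, by = 1000 / rate)
  gaze_trace(trial_id, t, rep(x, length(t)), rep(y, length(t)), rate_hz = rate)
}

# Trace with one injected saccade (uses the package waveform so detection
# ground truth is known exactly).
one_saccade_trace <- function(amplitude = 10, onset_ms = 800,
                              duration_s = 3, direction = c(1, 0),
                              noise_sd = 0, trial_id = "s1") {
  rate <- 250
  t <- seq(0, duration_s * 1000 - 4, by = 4)
  wf <- simulate_saccade_waveform(amplitude, 1, rate)
  x <- rep(0, length(t)); y <- rep(0, length(t))
  i0 <- findInterval(onset_ms, t)
  idx <- i0 + seq_len(nrow(wf)) - 1L
  idx <- idx[idx <= length(t)]
  u <- direction / sqrt(sum(direction^2))
  x[idx] <- x[idx] + u[1L] * wf$s[seq_along(idx)]
  y[idx] <- y[idx] + u[2L] * wf$s[seq_along(idx)]
  if (max(idx) < length(t)) {
    rest <- (max(idx) + 1L):length(t)
    x[rest] <- x[rest] + u[1L] * amplitude
    y[rest] <- y[rest] + u[2L] * amplitude
  }
  if (noise_sd > 0) {
    x <- x + rnorm(length(t), 0, noise_sd)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  gaze_trace(trial_id, t, x, y, rate_hz = rate)
}

# Hand-built saccade event table (for rule-level tests, no traces involved).
make_saccades <- function(onset, offset, start_x, start_y, end_x, end_y,
                          blink = FALSE, trial_id = "t1") {
  n <- length(onset)
  amp <- sqrt((end_x - start_x)^2 + (end_y - start_y)^2)
  saccade_events(trial_id = rep(trial_id, n), onset_ms = onset,
                 offset_ms = offset, start_x = start_x, start_y = start_y,
                 end_x = end_x, end_y = end_y, amplitude = amp,
                 peak_velocity = pmax(40, amp * 50),
                 contains_blink = rep_len(blink, n), ordinal = seq_len(n))
}

# Independent O(n^2) pair-scan oracle for square-wave jerks: iterates every
# ordered pair in lexicographic order under the same one-pairing-per-saccade
# constraint, re-deriving the rule predicates from scratch.
swj_bruteforce <- function(saccades, target_xy, max_amplitude = 2,
                           max_interval_ms = 300, max_amp_diff = 0.75) {
  s <- as.data.frame(saccades)
  n <- nrow(s)
  if (n < 2L) return(0L)
  dist_to <- function(x, y) sqrt((x - target_xy[1L])^2 + (y - target_xy[2L])^2)
  used <- rep(FALSE, n)
  count <- 0L
  for (i in seq_len(n)) {
    if (used[i]) next
    for (j in seq_len(n)) {
      if (j <= i || used[j] || used[i]) next
      ok <- s$amplitude[i] < max_amplitude &&
        s$amplitude[j] < max_amplitude &&
        dist_to(s$end_x[i], s$end_y[i]) > dist_to(s$start_x[i], s$start_y[i]) &&
        dist_to(s$end_x[j], s$end_y[j]) < dist_to(s$start_x[j], s$start_y[j]) &&
        (s$onset_ms[j] - s$offset_ms[i]) >= 0 &&
        (s$onset_ms[j] - s$offset_ms[i]) < max_interval_ms &&
        abs(s$amplitude[j] - s$amplitude[i]) < max_amp_diff
      if (ok) {
        used[i] <- used[j] <- TRUE
        count <- count + 1L
      }
    }
  }
  count
}

# Random saccade event list for property tests (amplitudes straddling the
# 2-deg gate, random geometry, ordered onsets).
random_saccade_list <- function(n, target_xy = c(0, 0)) {
  onset <- cumsum(runif(n, 40, 500))
  offset <- onset + runif(n, 15, 45)
  sx <- rnorm(n, target_xy[1L], 1); sy <- rnorm(n, target_xy[2L], 1)
  th <- runif(n, 0, 2 * pi); amp <- runif(n, 0.2, 3)
  make_saccades(onset, offset, sx, sy, sx + amp * cos(th), sy + amp * sin(th))
}

# Exhaustive ROC oracle: evaluates accuracy at every cutoff candidate in
# both directions by direct confusion-matrix counting.
roc_bruteforce <- function(scores, labels) {
  u <- sort(unique(scores))
  cuts <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  best_acc <- -1; best_sens <- -1
  for (dir in c(">", "<")) for (cut in cuts) {
    pred <- if (dir == ">") scores > cut else scores < cut
    acc <- mean(pred == labels)
    sens <- sum(pred & labels) / sum(labels)
    if (acc > best_acc || (acc == best_acc && sens > best_sens)) {
      best_acc <- acc; best_sens <- sens
    }
  }
  list(accuracy = best_acc, sensitivity = best_sens)
}

# Quick small-cohort profiles for pipeline-level tests.
tiny_profiles <- function(n = 3) {
  p <- default_profiles(n, n, n)
  p
}

# Reduced-trial config to keep pipeline tests fast.
fast_cfg <- function() {
  cfg <- default_config()
  cfg$n_fixation_trials <- 2
  cfg$n_saccade_blocks <- 1
  cfg$n_pursuit_trials <- 2
  cfg
}
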