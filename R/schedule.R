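# Task schedule: trial records for the fixation, gap/overlap saccade and
# sinusoidal pursuit tasks.

SACCADE_TARGETS <- rbind(
  data.frame(target_x = c(-15, -10, -5, 5, 10, 15), target_y = 0),
  data.frame(target_x = 0, target_y = c(-10, -5, 5, 10)))

#' Build the task schedule
#'
#' Fixation: one practice plus three scored 10 s trials at the centre.
#' Saccade: four blocks of ten trials; each block uses all ten target
#' locations exactly once (5, 10, 15 deg horizontal and 5, 10 deg vertical,
#' both signs) in randomized order, with the gap/overlap condition
#' alternating over blocks in an ABBA design, so each location appears
#' twice per condition. The central fixation point lasts 500 ms; target
#' onset is 200 ms after fixation offset (gap) or 200 ms before it
#' (overlap). Pursuit: two practice then six scored 10 s trials
#' (2.5 cycles at 0.25 Hz, half-range 10 deg), alternating
#' horizontal/vertical.
#'
#' @param cfg configuration from [load_config()].
#' @param seed optional seed for the within-block randomization.
#' @return data.frame of trial records (one row per trial) with columns
#'   `trial_id`, `task`, `condition`, `block`, `is_practice`, `target_x`,
#'   `target_y`, `eccentricity`, `fixation_offset_ms`, `target_onset_ms`,
#'   `pursuit_axis`, `pursuit_freq_hz`, `pursuit_amplitude_deg`,
#'   `pursuit_duration_s`.
#' @export
build_task_schedule <- function(cfg = default_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blank <- function(n) rep(NA_real_, n)
  fix_n <- cfg$n_fixation_trials + 1L
  fixation <- data.frame(
    trial_id = sprintf("fix%02d", seq_len(fix_n)),
    task = "fixation", condition = "none",
    block = NA_integer_, is_practice = seq_len(fix_n) == 1L,
    target_x = 0, target_y = 0, eccentricity = 0,
    fixation_offset_ms = blank(fix_n), target_onset_ms = blank(fix_n),
    pursuit_axis = NA_character_, pursuit_freq_hz = blank(fix_n),
    pursuit_amplitude_deg = blank(fix_n),
    pursuit_duration_s = cfg$fixation_trial_s)
  n_blocks <- cfg$n_saccade_blocks
  abba <- rep(c("gap", "overlap", "overlap", "gap"), length.out = n_blocks)
  fix_off <- cfg$fixation_point_duration_ms
  gap_off <- cfg$gap_overlap_offset_ms
  sacc <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    loc <- SACCADE_TARGETS[sample.int(nrow(SACCADE_TARGETS)), , drop = FALSE]
    cond <- abba[b]
    data.frame(
      trial_id = sprintf("sac%02d", (b - 1L) * nrow(loc) + seq_len(nrow(loc))),
      task = "saccade", condition = cond, block = b, is_practice = FALSE,
      target_x = loc$target_x, target_y = loc$target_y,
      eccentricity = pmax(abs(loc$target_x), abs(loc$target_y)),
      fixation_offset_ms = fix_off,
      target_onset_ms = if (cond == "gap") fix_off + gap_off else fix_off - gap_off,
      pursuit_axis = NA_character_, pursuit_freq_hz = NA_real_,
      pursuit_amplitude_deg = NA_real_, pursuit_duration_s = NA_real_)
  }))
  pur_n <- cfg$n_pursuit_trials + 2L
  axes <- rep(c("horizontal", "vertical"), length.out = pur_n)
  pursuit <- data.frame(
    trial_id = sprintf("pur%02d", seq_len(pur_n)),
    task = "pursuit", condition = "none",
    block = NA_integer_, is_practice = seq_len(pur_n) <= 2L,
    target_x = 0, target_y = 0, eccentricity = 0,
    fixation_offset_ms = NA_real_, target_onset_ms = NA_real_,
    pursuit_axis = axes, pursuit_freq_hz = cfg$pursuit_freq_hz,
    pursuit_amplitude_deg = cfg$pursuit_amplitude_deg,
    pursuit_duration_s = cfg$pursuit_trial_s)
  out <- rbind(fixation, sacc, pursuit)
  rownames(out) <- NULL
  out
}
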