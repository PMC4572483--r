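#' Default pipeline configuration
#'
#' Central registry of tunable parameters with the task-design and parser
#' defaults: 30 deg/s velocity and 8000 deg/s^2 acceleration thresholds,
#' 250 Hz sampling, 200 ms gap/overlap stimulus offsets, 0.25 Hz sinusoidal
#' pursuit with 10 deg half-range, 50 ms exclusion padding, the [-1, +2]
#' pursuit-gain trim and the square-wave-jerk rule constants.
#'
#' @return a named list of parameters.
#' @export
default_config <- function() {
  list(
    rate_hz = 250,
    velocity_threshold = 30,        # deg/s
    acceleration_threshold = 8000,  # deg/s^2
    min_saccade_duration_ms = 8,
    min_fixation_duration_ms = 40,
    blink_pad_ms = 50,
    smooth_window = 1,              # samples; 1 = no pre-smoothing, 3 = moving average
    # fixation task
    fixation_trial_s = 10,
    n_fixation_trials = 3,          # scored (one practice discarded upstream)
    swj_max_amplitude = 2,          # deg, strict <
    swj_max_interval_ms = 300,
    swj_max_amp_diff = 0.75,        # deg, strict <
    swj_interval_anchor = "offset_onset",  # or "onset_onset"
    intrusion_min_amplitude = 2,    # deg, strict >
    # saccade task
    gap_overlap_offset_ms = 200,
    fixation_point_duration_ms = 500,
    target_window_deg = 2.5,
    response_window_ms = 5000,
    main_start_max_deg = 2.5,
    main_direction_max_deg = 45,
    main_max_ordinal = 5,           # sixth saccade or later => discard
    n_saccade_blocks = 4,
    trials_per_block = 10,
    # pursuit task
    pursuit_freq_hz = 0.25,
    pursuit_amplitude_deg = 10,     # half-range
    pursuit_trial_s = 10,
    n_pursuit_trials = 6,
    pursuit_pad_ms = 50,
    gain_trim_lo = -1,
    gain_trim_hi = 2,
    min_target_speed = 2,           # deg/s; 0 reproduces the literal procedure
    gain_smooth_window = 3,         # samples of pre-smoothing for gain velocity
    # statistics
    trim_z = 2,
    impairment_sd = 2
  )
}

#' Load a configuration file
#'
#' The format is a flat `key: value` text file (one pair per line, `#`
#' comments, blank lines ignored) layered over [default_config()]. Unknown
#' keys are rejected, as are out-of-range values.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return validated parameter list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1L]]
      if (length(m) != 3L) stop("config: unparseable line: ", ln)
      key <- m[2L]; raw <- trimws(m[3L])
      if (!key %in% names(cfg)) stop("config: unknown key: ", key)
      num <- suppressWarnings(as.numeric(raw))
      cfg[[key]] <- if (!is.na(num)) num else raw
    }
  }
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  pos <- c("rate_hz", "velocity_threshold", "acceleration_threshold",
           "min_saccade_duration_ms", "min_fixation_duration_ms",
           "fixation_trial_s", "swj_max_amplitude", "swj_max_interval_ms",
           "swj_max_amp_diff", "gap_overlap_offset_ms", "target_window_deg",
           "response_window_ms", "pursuit_freq_hz", "pursuit_amplitude_deg",
           "pursuit_trial_s", "trim_z", "impairment_sd")
  for (k in pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("config: ", k, " must be a positive number, got ", format(cfg[[k]]))
    }
  }
  nonneg <- c("blink_pad_ms", "pursuit_pad_ms", "min_target_speed")
  for (k in nonneg) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) {
      stop("config: ", k, " must be non-negative")
    }
  }
  if (!cfg$swj_interval_anchor %in% c("offset_onset", "onset_onset")) {
    stop("config: swj_interval_anchor must be offset_onset or onset_onset")
  }
  if (cfg$gain_trim_hi <= cfg$gain_trim_lo) {
    stop("config: gain_trim_hi must exceed gain_trim_lo")
  }
  invisible(cfg)
}

#' Parser parameters extracted from a configuration
#'
#' @param cfg a configuration list from [load_config()].
#' @return list with the event-detection thresholds.
#' @export
parser_params <- function(cfg = default_config()) {
  p <- cfg[c("velocity_threshold", "acceleration_threshold",
             "min_saccade_duration_ms", "min_fixation_duration_ms",
             "blink_pad_ms", "smooth_window")]
  stopifnot(p$velocity_threshold > 0, p$acceleration_threshold > 0,
            p$min_saccade_duration_ms > 0, p$min_fixation_duration_ms > 0)
  p
}
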