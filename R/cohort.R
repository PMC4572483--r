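# Cohort assembly: simulate full groups with reproducible per-participant
# substreams, and the metric-extraction pipeline turning traces into the
# long observation table that feeds the statistics stage.

#' Simulate a complete cohort
#'
#' For each profile, draws participants (age, a participant-level latency
#' median around the group's, a pseudo neuropsychological score correlated
#' with that latency at the profile's loading), builds a per-participant
#' randomized task schedule and simulates every trial. Reproducible from a
#' single root seed: per-participant sub-seeds are drawn once up front.
#'
#' @param profiles list of [cohort_profile()]s (default [default_profiles()]).
#' @param seed root integer seed.
#' @param cfg configuration (trial counts, task geometry).
#' @return list of class `gaze_cohort`: `participants` (data.frame),
#'   `schedule` (data.frame with `participant_id`), `traces` (named list of
#'   [gaze_trace()], key `participant_id::trial_id`), `truth` (named list).
#' @export
make_cohort <- function(profiles = default_profiles(), seed = 1,
                        cfg = default_config()) {
  set.seed(seed)
  total_n <- sum(vapply(profiles, `[[`, numeric(1L), "n_participants"))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, total_n)
  participants <- list(); schedule <- list()
  traces <- list(); truth <- list()
  pidx <- 0L
  for (prof in profiles) {
    for (k in seq_len(prof$n_participants)) {
      pidx <- pidx + 1L
      pid <- sprintf("%s%02d", prof$group_label, k)
      set.seed(sub_seeds[pidx])
      age <- stats::rnorm(1, prof$age_mean, prof$age_sd)
      zlat <- stats::rnorm(1)
      lat_med <- prof$latency_median_ms * exp(0.15 * zlat)
      l <- prof$pseudo_score_loading
      pseudo <- -l * zlat + sqrt(max(0, 1 - l^2)) * stats::rnorm(1)
      sched <- build_task_schedule(cfg)
      sched$participant_id <- pid
      schedule[[pidx]] <- sched
      for (i in seq_len(nrow(sched))) {
        trial <- as.list(sched[i, ])
        sim <- switch(trial$task,
          fixation = simulate_fixation_trial(
            prof, c(trial$target_x, trial$target_y), trial$trial_id,
            duration_s = cfg$fixation_trial_s),
          saccade = simulate_saccade_trial(
            prof, trial, latency_median_ms = lat_med),
          pursuit = simulate_pursuit_trial(prof, trial))
        key <- paste0(pid, "::", trial$trial_id)
        traces[[key]] <- sim$trace
        truth[[key]] <- sim$truth
      }
      participants[[pidx]] <- data.frame(
        participant_id = pid, group = prof$group_label, age = age,
        latency_median_true = lat_med, pseudo_score = pseudo)
    }
  }
  structure(list(participants = do.call(rbind, participants),
                 schedule = do.call(rbind, schedule),
                 traces = traces, truth = truth, seed = seed),
            class = "gaze_cohort")
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf("<gaze_cohort> %d participants (%s), %d trials, seed %s\n",
              nrow(x$participants),
              paste(sprintf("%s n=%d", names(table(x$participants$group)),
                            table(x$participants$group)), collapse = ", "),
              length(x$traces), format(x$seed)))
  invisible(x)
}

#' Extract all oculomotor metrics from a cohort
#'
#' Runs event detection on every scored trial and computes the task
#' metrics, returning a long observation table (one row per participant x
#' trial x metric) plus the per-trial main-saccade selection results.
#' Practice trials are discarded.
#'
#' @param cohort a `gaze_cohort` (or compatible list of traces + schedule +
#'   participants).
#' @param cfg configuration.
#' @return list: `rows` (data.frame: `participant_id`, `group`, `age`,
#'   `trial_id`, `task`, `condition`, `eccentricity`, `axis`, `metric`,
#'   `value`, `saccade_amplitude`), `main_results` (named list, one
#'   [identify_main_saccade()] result per saccade trial).
#' @export
compute_metrics <- function(cohort, cfg = default_config()) {
  params <- parser_params(cfg)
  rows <- list(); main_results <- list()
  part <- cohort$participants
  for (p in seq_len(nrow(part))) {
    pid <- part$participant_id[p]
    grp <- part$group[p]; age <- part$age[p]
    sched <- cohort$schedule[cohort$schedule$participant_id == pid &
                               !cohort$schedule$is_practice, , drop = FALSE]
    row_of <- function(trial, metric, value, amp = NA_real_) {
      data.frame(participant_id = pid, group = grp, age = age,
                 trial_id = trial$trial_id, task = trial$task,
                 condition = trial$condition,
                 eccentricity = trial$eccentricity,
                 axis = if (is.na(trial$pursuit_axis)) NA_character_ else trial$pursuit_axis,
                 metric = metric, value = value, saccade_amplitude = amp)
    }
    fix_trials <- list()
    for (i in seq_len(nrow(sched))) {
      trial <- as.list(sched[i, ])
      tr <- cohort$traces[[paste0(pid, "::", trial$trial_id)]]
      ev <- detect_events(tr, params)
      if (trial$task == "fixation") {
        swj <- count_square_wave_jerks(
          ev$saccades, c(trial$target_x, trial$target_y),
          max_amplitude = cfg$swj_max_amplitude,
          max_interval_ms = cfg$swj_max_interval_ms,
          max_amp_diff = cfg$swj_max_amp_diff,
          interval_anchor = cfg$swj_interval_anchor)
        rows[[length(rows) + 1L]] <- row_of(trial, "swj_count", swj$count)
        rows[[length(rows) + 1L]] <- row_of(
          trial, "intrusive_saccades",
          count_large_intrusive_saccades(ev$saccades, cfg$intrusion_min_amplitude))
        fix_trials[[length(fix_trials) + 1L]] <-
          list(span = trace_span(tr), saccades = ev$saccades)
      } else if (trial$task == "saccade") {
        ttf <- time_to_first_target_fixation(
          trial, ev$fixations, window_deg = cfg$target_window_deg,
          response_window_ms = cfg$response_window_ms)
        rows[[length(rows) + 1L]] <- row_of(trial, "time_to_target_ms", ttf)
        res <- identify_main_saccade(
          trial, ev$saccades, start_max_deg = cfg$main_start_max_deg,
          direction_max_deg = cfg$main_direction_max_deg,
          max_ordinal = cfg$main_max_ordinal)
        main_results[[paste0(pid, "::", trial$trial_id)]] <- res
        if (identical(res$status, "selected")) {
          rows[[length(rows) + 1L]] <- row_of(trial, "latency_ms", res$latency_ms)
          rows[[length(rows) + 1L]] <- row_of(trial, "amplitude_error_deg",
                                              res$amplitude_error_deg)
          rows[[length(rows) + 1L]] <- row_of(trial, "peak_velocity",
                                              res$peak_velocity,
                                              amp = res$saccade$amplitude)
        }
        rows[[length(rows) + 1L]] <- row_of(
          trial, "n_saccades", count_trial_saccades(trial, ev$saccades))
      } else if (trial$task == "pursuit") {
        pres <- pursuit_trial_result(tr, trial, params, cfg)
        rows[[length(rows) + 1L]] <- row_of(trial, "pursuit_gain", pres$mean_gain)
        rows[[length(rows) + 1L]] <- row_of(trial, "pursuit_saccades",
                                            pres$n_saccades)
      }
    }
    if (length(fix_trials)) {
      trial0 <- as.list(sched[sched$task == "fixation", ][1L, ])
      trial0$trial_id <- "all"
      rows[[length(rows) + 1L]] <- row_of(
        trial0, "longest_fixation_ms", longest_fixation_period(fix_trials))
    }
  }
  list(rows = do.call(rbind, rows), main_results = main_results)
}

#' Participant-level metric summaries
#'
#' Mean of each metric per participant (for impairment classification, ROC
#' and correlation analyses, which operate at participant level).
#'
#' @param rows long table from [compute_metrics()].
#' @return wide data.frame, one row per participant, one column per metric
#'   plus `group` and `age`.
#' @export
participant_summaries <- function(rows) {
  agg <- stats::aggregate(value ~ participant_id + metric, data = rows,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  wide <- stats::reshape(agg, idvar = "participant_id", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  meta <- unique(rows[, c("participant_id", "group", "age")])
  out <- merge(meta, wide, by = "participant_id", sort = TRUE)
  rownames(out) <- NULL
  out
}
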