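# Saccade-task metrics: target acquisition, main-saccade algorithm,
# transforms, counts, gap/overlap contrast.

sac_trial <- function(condition = "gap", target_x = 10, target_y = 0) {
  list(trial_id = "tr1", task = "saccade", condition = condition,
       target_x = target_x, target_y = target_y,
       eccentricity = max(abs(target_x), abs(target_y)),
       fixation_offset_ms = 500,
       target_onset_ms = if (condition == "gap") 700 else 300)
}

test_that("time to first target fixation: arithmetic, missing, clamped", {
  trial <- sac_trial()
  trial$target_onset_ms <- 300
  f <- fixation_events(trial_id = "tr1", onset_ms = c(0, 650),
                       offset_ms = c(280, 1400),
                       mean_x = c(0, 10.2), mean_y = c(0, 0))
  expect_equal(time_to_first_target_fixation(trial, f), 350)

  f2 <- fixation_events(trial_id = "tr1", onset_ms = 650, offset_ms = 1400,
                        mean_x = 5, mean_y = 5)
  expect_true(is.na(time_to_first_target_fixation(trial, f2)))

  # fixation on target already ongoing at target onset clamps to 0
  f3 <- fixation_events(trial_id = "tr1", onset_ms = 100, offset_ms = 900,
                        mean_x = 9.5, mean_y = 0)
  expect_equal(time_to_first_target_fixation(trial, f3), 0)

  # fixation starting after the 5000 ms window does not count
  f4 <- fixation_events(trial_id = "tr1", onset_ms = 5600, offset_ms = 6000,
                        mean_x = 10, mean_y = 0)
  expect_true(is.na(time_to_first_target_fixation(trial, f4)))
})

test_that("main-saccade filter rules select, discard, or find no candidate", {
  trial <- sac_trial("gap")  # target onset 700
  good <- make_saccades(onset = 900, offset = 950, start_x = 0, start_y = 0,
                        end_x = 9, end_y = 0)
  r <- identify_main_saccade(trial, good)
  expect_identical(r$status, "selected")
  expect_equal(r$latency_ms, 200)
  expect_equal(r$amplitude_error_deg, -1)

  # s1 before target onset, s2 valid -> s2 selected
  s <- make_saccades(onset = c(650, 900), offset = c(680, 950),
                     start_x = c(0, 0.5), start_y = c(0, 0),
                     end_x = c(0.5, 9.5), end_y = c(0, 0))
  r2 <- identify_main_saccade(trial, s)
  expect_identical(r2$status, "selected")
  expect_equal(r2$saccade$ordinal, 2L)

  # start 3 deg from centre is removed
  far <- make_saccades(onset = 900, offset = 950, start_x = 3, start_y = 0,
                       end_x = 10, end_y = 0)
  expect_identical(identify_main_saccade(trial, far)$status, "no_candidate")

  # wrong direction (> 45 deg) removed
  wrong <- make_saccades(onset = 900, offset = 950, start_x = 0, start_y = 0,
                         end_x = 0, end_y = 8)
  expect_identical(identify_main_saccade(trial, wrong)$status, "no_candidate")

  # blink-containing removed
  blk <- make_saccades(onset = 900, offset = 950, start_x = 0, start_y = 0,
                       end_x = 9, end_y = 0, blink = TRUE)
  expect_identical(identify_main_saccade(trial, blk)$status, "no_candidate")

  # first survivor is the sixth parsed saccade -> trial discarded
  s6 <- make_saccades(onset = 700 + 30 * (1:6) - 20, offset = 700 + 30 * (1:6),
                      start_x = rep(0, 6), start_y = rep(0, 6),
                      end_x = c(0, 0, 0, 0, 0, 9), end_y = c(1, 1, 1, 1, 1, 0))
  s6$contains_blink[1:5] <- TRUE
  r6 <- identify_main_saccade(trial, s6)
  expect_identical(r6$status, "discarded")
})

test_that("main-saccade filter is order-insensitive (independent predicates)", {
  set.seed(21)
  trial <- sac_trial("gap", target_x = 10)
  for (rep in 1:40) {
    n <- sample(1:8, 1L)
    onset <- sort(runif(n, 400, 2000))
    th <- runif(n, 0, 2 * pi)
    amp <- runif(n, 0.5, 12)
    sx <- rnorm(n, 0, 2); sy <- rnorm(n, 0, 2)
    s <- make_saccades(onset, onset + 40, sx, sy,
                       sx + amp * cos(th), sy + amp * sin(th))
    s$contains_blink <- runif(n) < 0.2
    res <- identify_main_saccade(trial, s)
    # oracle: apply predicates independently, pick first survivor
    keep <- !s$contains_blink & s$onset_ms >= trial$target_onset_ms &
      sqrt(s$start_x^2 + s$start_y^2) <= 2.5
    ang <- atan2(s$end_y - s$start_y, s$end_x - s$start_x) -
      atan2(trial$target_y, trial$target_x)
    keep <- keep & (abs(atan2(sin(ang), cos(ang))) * 180 / pi) <= 45
    status <- if (!any(keep)) "no_candidate"
    else if (s$ordinal[which(keep)[1L]] > 5) "discarded" else "selected"
    expect_identical(res$status, status)
    if (status == "selected") {
      expect_identical(res$saccade$ordinal, s$ordinal[which(keep)[1L]])
    }
  }
})

test_that("latency, amplitude error and counts", {
  trial <- sac_trial("overlap")  # target onset 300
  s <- make_saccades(onset = 900, offset = 950, start_x = 0, start_y = 0,
                     end_x = 10, end_y = 0)
  r <- identify_main_saccade(trial, s)
  expect_equal(saccade_latency(r), 600)
  expect_equal(amplitude_error(r, trial), 0)
  expect_true(is.na(saccade_latency(list(status = "no_candidate"))))

  r$saccade$amplitude <- 7.5
  expect_equal(amplitude_error(r, trial), -2.5)
  r$saccade$amplitude <- 11
  expect_equal(amplitude_error(r, trial), 1)

  # saccade counting: after onset, no blink, > 2 deg
  s2 <- make_saccades(onset = c(100, 400, 600, 800, 1000),
                      offset = c(140, 440, 640, 840, 1040),
                      start_x = rep(0, 5), start_y = rep(0, 5),
                      end_x = c(5, 3, 1.5, 4, 2.5), end_y = rep(0, 5))
  s2$contains_blink[4L] <- TRUE
  expect_equal(count_trial_saccades(trial, s2), 2L)
  # brute-force filter oracle
  bf <- sum(s2$onset_ms >= trial$target_onset_ms & !s2$contains_blink &
              s2$amplitude > 2)
  expect_equal(count_trial_saccades(trial, s2), bf)
  expect_equal(count_trial_saccades(list(target_onset_ms = 2000), s2), 0L)
})

test_that("sqrt transform and +-2 SD trim", {
  # constant vector: SD 0, nothing removed
  r <- sqrt_transform_trim(rep(4, 5), rep("a", 5))
  expect_true(all(r$keep))
  expect_equal(r$transformed, rep(2, 5))

  # an extreme outlier is removed, the rest kept (n must exceed 5: with the
  # n-1 sample SD the largest attainable |z| is (n-1)/sqrt(n))
  vals <- c(100, 121, 144, 169, 196, 225, 10000)
  r2 <- sqrt_transform_trim(vals, rep("a", 7))
  # reference recomputation
  tv <- sqrt(vals)
  z <- (tv - mean(tv)) / sd(tv)
  expect_identical(r2$keep, abs(z) <= 2)
  expect_equal(sum(!r2$keep), 1L)

  # idempotent on its own output
  kept <- vals[r2$keep]
  r3 <- sqrt_transform_trim(kept, rep("a", length(kept)))
  expect_true(all(r3$keep))

  # per-group independence
  g <- rep(c("a", "b"), c(7, 5))
  v <- c(100, 121, 144, 169, 196, 225, 10000, 1, 1.2, 1.1, 0.9, 1)
  r4 <- sqrt_transform_trim(v, g)
  expect_equal(sum(!r4$keep[g == "a"]), 1L)
  expect_true(all(r4$keep[g == "b"]))

  # small group: warning, trim skipped
  expect_warning(r5 <- sqrt_transform_trim(c(1, 100), c("a", "a")), "< 3")
  expect_true(all(r5$keep))

  expect_error(sqrt_transform_trim(c(-1, 2), c("a", "a")), "negative")
})

test_that("removal rate and gap/overlap contrast", {
  res <- c(replicate(36, list(status = "selected"), simplify = FALSE),
           replicate(3, list(status = "discarded"), simplify = FALSE),
           replicate(1, list(status = "no_candidate"), simplify = FALSE))
  expect_equal(removal_rate(res), 0.10)
  expect_equal(removal_rate(replicate(40, list(status = "selected"),
                                      simplify = FALSE)), 0)

  rows <- data.frame(
    participant_id = rep(c("p1", "p2"), each = 4),
    group = "g",
    condition = rep(c("gap", "gap", "overlap", "overlap"), 2),
    value = c(200, 220, 290, 310, 180, 200, 240, 260))
  gc <- gap_overlap_effect(rows)
  expect_equal(gc$per_participant$contrast, c(90, 60))
  expect_equal(gc$by_group$mean_contrast, 75)

  # identical conditions -> 0; label swap flips the sign
  rows0 <- rows; rows0$value <- rep(c(200, 220, 200, 220), 2)
  expect_equal(gap_overlap_effect(rows0)$by_group$mean_contrast, 0)
  rows_sw <- rows
  rows_sw$condition <- ifelse(rows$condition == "gap", "overlap", "gap")
  expect_equal(gap_overlap_effect(rows_sw)$by_group$mean_contrast, -75)

  # missing condition excluded with warning
  rows_m <- rows[!(rows$participant_id == "p2" & rows$condition == "overlap"), ]
  expect_warning(gcm <- gap_overlap_effect(rows_m), "p2")
  expect_equal(nrow(gcm$per_participant), 1L)
})

test_that("simulated latency and overlap penalty are recovered within 2 SEM", {
  prof <- default_profiles()$control
  prof$wrong_dir_prob <- 0; prof$pretarget_rate <- 0; prof$blink_rate <- 0
  prof$overlap_penalty_ms <- 80
  sched <- build_task_schedule(seed = 5)
  sac <- sched[sched$task == "saccade", ]
  n <- 60
  lat <- true_lat <- numeric(0); cond <- character(0)
  set.seed(17)
  for (i in seq_len(n)) {
    trial <- as.list(sac[((i - 1L) %% nrow(sac)) + 1L, ])
    sim <- simulate_saccade_trial(prof, trial)
    ev <- detect_events(sim$trace)
    r <- identify_main_saccade(trial, ev$saccades)
    if (r$status != "selected") next
    lat <- c(lat, r$latency_ms); true_lat <- c(true_lat, sim$truth$true_latency_ms)
    cond <- c(cond, trial$condition)
  }
  expect_gt(length(lat), 0.8 * n)
  # measured latency tracks true latency trial by trial (parser delay < 20 ms)
  expect_lt(mean(abs(lat - true_lat)), 20)
  # overlap - gap contrast recovers the 80 ms penalty within 2 SEM
  d <- mean(lat[cond == "overlap"]) - mean(lat[cond == "gap"])
  sem <- sqrt(var(lat[cond == "overlap"]) / sum(cond == "overlap") +
                var(lat[cond == "gap"]) / sum(cond == "gap"))
  expect_lt(abs(d - 80), 2 * sem)
})
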