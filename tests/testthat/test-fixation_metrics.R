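# Square-wave jerks, intrusive saccades, longest fixation.

test_that("SWJ rule gates behave as specified", {
  expect_equal(count_square_wave_jerks(saccade_events(), c(0, 0))$count, 0L)

  # 1.0 deg away at 0-30 ms, 1.1 deg back at 180 ms: one SWJ
  s <- make_saccades(onset = c(0, 180), offset = c(30, 210),
                     start_x = c(0, 1), start_y = c(0, 0),
                     end_x = c(1, -0.1), end_y = c(0, 0))
  r <- count_square_wave_jerks(s, c(0, 0))
  expect_equal(r$count, 1L)
  expect_equal(r$pairs$inter_saccade_interval_ms, 150)
  expect_equal(r$pairs$amplitude_difference_deg, 0.1, tolerance = 1e-9)

  # amplitude difference 0.9 >= 0.75: no SWJ
  s2 <- make_saccades(onset = c(0, 180), offset = c(30, 210),
                      start_x = c(0, 1), start_y = c(0, 0),
                      end_x = c(1, -0.9), end_y = c(0, 0))
  expect_equal(count_square_wave_jerks(s2, c(0, 0))$count, 0L)

  # first saccade 2.5 deg: fails the < 2 deg gate
  s3 <- make_saccades(onset = c(0, 180), offset = c(30, 210),
                      start_x = c(0, 2.5), start_y = c(0, 0),
                      end_x = c(2.5, 0.1), end_y = c(0, 0))
  expect_equal(count_square_wave_jerks(s3, c(0, 0))$count, 0L)

  # return after 300 ms: too late
  s4 <- make_saccades(onset = c(0, 340), offset = c(30, 370),
                      start_x = c(0, 1), start_y = c(0, 0),
                      end_x = c(1, 0), end_y = c(0, 0))
  expect_equal(count_square_wave_jerks(s4, c(0, 0))$count, 0L)
})

test_that("greedy pairing uses each saccade at most once", {
  # away, toward, toward: second toward must remain unpaired
  s <- make_saccades(onset = c(0, 150, 300), offset = c(30, 180, 330),
                     start_x = c(0, 1, 1), start_y = c(0, 0, 0),
                     end_x = c(1, 0, 0), end_y = c(0, 0, 0))
  expect_equal(count_square_wave_jerks(s, c(0, 0))$count, 1L)
})

test_that("SWJ counter matches the brute-force pair-scan oracle", {
  set.seed(11)
  for (rep in 1:150) {
    n <- sample(2:20, 1L)
    s <- random_saccade_list(n)
    expect_identical(count_square_wave_jerks(s, c(0, 0))$count,
                     swj_bruteforce(s, c(0, 0)))
  }
})

test_that("onset-to-onset anchor is configurable", {
  # gap offset->onset = 280 but onset->onset = 310
  s <- make_saccades(onset = c(0, 310), offset = c(30, 340),
                     start_x = c(0, 1), start_y = c(0, 0),
                     end_x = c(1, 0), end_y = c(0, 0))
  expect_equal(count_square_wave_jerks(s, c(0, 0),
                                       interval_anchor = "offset_onset")$count, 1L)
  expect_equal(count_square_wave_jerks(s, c(0, 0),
                                       interval_anchor = "onset_onset")$count, 0L)
})

test_that("large intrusive saccades: amplitude and blink gates", {
  s <- make_saccades(onset = c(0, 500, 1000), offset = c(40, 540, 1040),
                     start_x = c(0, 0, 0), start_y = c(0, 0, 0),
                     end_x = c(0.5, 1.9, 0), end_y = c(0, 0, 0))
  expect_equal(count_large_intrusive_saccades(s), 0L)

  s2 <- make_saccades(onset = c(0, 500, 1000), offset = c(40, 540, 1040),
                      start_x = c(0, 0, 0), start_y = c(0, 0, 0),
                      end_x = c(2.5, 3.0, 1.0), end_y = c(0, 0, 0))
  expect_equal(count_large_intrusive_saccades(s2), 2L)

  s3 <- make_saccades(onset = c(0, 500), offset = c(40, 540),
                      start_x = c(0, 0), start_y = c(0, 0),
                      end_x = c(2.5, 3.0), end_y = c(0, 0),
                      blink = c(TRUE, FALSE))
  expect_equal(count_large_intrusive_saccades(s3), 1L)
})

test_that("large + small counts partition blink-free saccades", {
  set.seed(3)
  for (rep in 1:20) {
    s <- random_saccade_list(sample(1:15, 1L))
    s$contains_blink <- runif(nrow(s)) < 0.2
    n_large <- count_large_intrusive_saccades(s)
    n_small <- sum(!s$contains_blink & s$amplitude <= 2)
    expect_identical(n_large + n_small, sum(!s$contains_blink))
  }
})

test_that("longest fixation period across trials", {
  empty <- saccade_events()
  t1 <- list(span = c(0, 10000), saccades = empty)
  expect_equal(longest_fixation_period(list(t1)), 10000)

  s <- make_saccades(onset = c(1800, 7500), offset = c(2000, 7600),
                     start_x = c(0, 0), start_y = c(0, 0),
                     end_x = c(1, 1), end_y = c(0, 0))
  t2 <- list(span = c(0, 10000), saccades = s)
  expect_equal(longest_fixation_period(list(t2)), 5500)

  # max over trials
  s3 <- make_saccades(onset = 3000, offset = 3100, start_x = 0, start_y = 0,
                      end_x = 1, end_y = 0)
  t3 <- list(span = c(0, 10000), saccades = s3)  # max gap 6900
  expect_equal(longest_fixation_period(list(t2, t3)), 6900)

  expect_error(longest_fixation_period(list()), "no trials")
})

test_that("injected SWJ rate is recovered end to end within +-1 per trial", {
  prof <- default_profiles()$control
  prof$swj_rate <- 3; prof$intrusion_rate <- 0.5; prof$blink_rate <- 0.3
  inj <- det <- numeric(40)
  for (s in 1:40) {
    sim <- simulate_fixation_trial(prof, seed = 500 + s)
    ev <- detect_events(sim$trace)
    inj[s] <- sim$truth$n_swj_injected
    det[s] <- count_square_wave_jerks(ev$saccades, c(0, 0))$count
  }
  expect_gte(mean(abs(inj - det) <= 1), 0.9)
  expect_lt(abs(mean(inj) - mean(det)), 0.75)
})
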