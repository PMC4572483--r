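# Group statistics, impairment classification, ROC.

make_rows <- function(n_per_group, groups = c("a", "b"), effect = 0,
                      age_effect = 0, sd = 1, trials = 4, seed = 1) {
  set.seed(seed)
  out <- list()
  for (gi in seq_along(groups)) {
    for (p in seq_len(n_per_group)) {
      pid <- paste0(groups[gi], p)
      age <- rnorm(1, 65 + 3 * (gi - 1), 5)
      base <- (gi - 1) * effect + age_effect * age + rnorm(1, 0, sd)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, group = groups[gi], age = age,
        value = base + rnorm(trials, 0, sd / 2))
    }
  }
  do.call(rbind, out)
}

test_that("group model: identical groups give near-zero contrast, p near 1", {
  rows <- make_rows(10, effect = 0, seed = 3)
  fit <- fit_group_model(rows)
  expect_lt(abs(fit$contrasts$estimate), 0.75)
  expect_gt(fit$contrasts$p, 0.05)
})

test_that("group model detects a 2-SD shift and respects age adjustment", {
  # power: 2 pooled-SD shift, n = 15/group
  hits <- 0L
  for (r in 1:40) {
    rows <- make_rows(15, effect = 2, sd = 1, seed = 100 + r)
    fit <- fit_group_model(rows)
    if (fit$contrasts$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)

  # age-confounded null: metric depends only on age, groups differ in age
  fp <- 0L
  for (r in 1:40) {
    rows <- make_rows(15, effect = 0, age_effect = 0.5, sd = 1, seed = 200 + r)
    fit <- fit_group_model(rows)
    if (fit$contrasts$p < 0.05) fp <- fp + 1L
  }
  expect_gte(1 - fp / 40, 0.9)
})

test_that("rank-deficient designs fail with the collinear term named", {
  rows <- make_rows(5, seed = 9)
  rows$dup <- rows$age
  expect_error(fit_group_model(rows, covariates = c("age", "dup")),
               "collinear|dup")
})

test_that("interaction test: null retained, effect detected, symmetric", {
  null_p <- eff_p <- numeric(25)
  for (r in 1:25) {
    rows <- make_rows(12, effect = 1, seed = 300 + r)
    rows$condition <- rep_len(c("gap", "overlap"), nrow(rows))
    # equal condition effect in both groups: interaction null
    rows$value <- rows$value + 0.5 * (rows$condition == "overlap")
    null_p[r] <- interaction_test(rows, "condition")$wald$p
    # triple the condition effect in group b
    rows2 <- rows
    rows2$value <- rows2$value +
      1.5 * (rows2$condition == "overlap") * (rows2$group == "b")
    eff_p[r] <- interaction_test(rows2, "condition")$wald$p
  }
  expect_lt(mean(null_p < 0.05), 0.25)
  expect_gte(mean(eff_p < 0.05), 0.9)

  # swapping group labels flips the pairwise interaction contrast sign
  rows <- make_rows(8, effect = 1, seed = 11)
  rows$condition <- rep_len(c("gap", "overlap"), nrow(rows))
  rows$value <- rows$value + (rows$condition == "overlap") * (rows$group == "b")
  it1 <- interaction_test(rows, "condition")
  rows_sw <- rows
  rows_sw$group <- ifelse(rows$group == "a", "b", "a")
  it2 <- interaction_test(rows_sw, "condition")
  expect_equal(it1$pairwise$estimate, -it2$pairwise$estimate, tolerance = 1e-8)
  expect_equal(it1$wald$p, it2$wald$p, tolerance = 1e-8)

  rows_empty <- rows[!(rows$group == "b" & rows$condition == "overlap"), ]
  expect_error(interaction_test(rows_empty, "condition"), "empty cell")
})

test_that("pairwise correlations: exact cases and affine invariance", {
  x <- data.frame(m = 1:10)
  y <- data.frame(s = 2 * (1:10) + 3)
  pc <- pairwise_correlations(x, y)
  expect_equal(unname(pc$r[1, 1]), 1)

  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  r1 <- pairwise_correlations(data.frame(a), data.frame(b))$r[1, 1]
  r2 <- pairwise_correlations(data.frame(a = 10 * a - 4),
                              data.frame(b = -2 * b + 7))$r[1, 1]
  expect_equal(abs(r1), abs(r2), tolerance = 1e-12)

  # zero-variance column reported missing
  pc0 <- pairwise_correlations(data.frame(c = rep(1, 10)), data.frame(b = 1:10))
  expect_true(is.na(pc0$r[1, 1]))

  # Bonferroni keeps family-wise error near nominal for independent nulls
  # (true FWER with 12 exact tests is 1 - (1 - 0.05/12)^12 ~ 0.049)
  set.seed(98)
  reps <- 300L
  fam_err <- 0L
  for (r in seq_len(reps)) {
    m <- as.data.frame(matrix(rnorm(20 * 3), 20))
    s <- as.data.frame(matrix(rnorm(20 * 4), 20))
    pc <- pairwise_correlations(m, s)
    if (any(pc$p_bonferroni < 0.05, na.rm = TRUE)) fam_err <- fam_err + 1L
  }
  expect_lte(fam_err / reps, 0.049 + 2.6 * sqrt(0.049 * 0.951 / reps))
})

test_that("Cohen's d closed forms and formula oracle", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(4)
  x <- rnorm(50, 1, 1); y <- rnorm(50, 0, 1)
  d <- cohens_d(x, y)
  sp <- sqrt(((49) * var(x) + 49 * var(y)) / 98)
  expect_equal(d, (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_true(is.na(cohens_d(c(1, 1, 1), c(1, 1))))
})

test_that("impairment classification: direction and strict 2 SD boundary", {
  expect_true(classify_impairment(260, 200, 25, "higher"))
  expect_false(classify_impairment(250, 200, 25, "higher"))  # exactly 2 SD
  expect_true(classify_impairment(2500, 5000, 1000, "lower"))
  expect_false(classify_impairment(3000, 5000, 1000, "lower"))
  expect_error(classify_impairment(1, NA, 1, "higher"), "unavailable")

  # about 2.3% of control-distributed scores flagged per one-sided metric
  set.seed(12)
  v <- rnorm(10000)
  frac <- mean(classify_impairment(v, 0, 1, "higher"))
  expect_lt(abs(frac - pnorm(-2)), 0.006)
})

test_that("multi-metric impairment rate uses strict > 1", {
  f <- matrix(FALSE, 15, 4)
  expect_equal(multi_metric_impairment_rate(f), 0)
  f[1:12, 1:2] <- TRUE
  expect_equal(multi_metric_impairment_rate(f), 12 / 15)
  f2 <- matrix(FALSE, 10, 4); f2[, 1] <- TRUE  # exactly one impaired metric
  expect_equal(multi_metric_impairment_rate(f2), 0)
})

test_that("ROC best cutoff: separable, degenerate and oracle-equivalent", {
  r <- roc_best_cutoff(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$accuracy, 1)
  expect_identical(r$direction, ">")
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 5)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)

  # identical distributions: accuracy = majority-class proportion
  r2 <- roc_best_cutoff(c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                        c(rep(TRUE, 3), rep(FALSE, 6)))
  expect_equal(r2$accuracy, 6 / 9)

  expect_error(roc_best_cutoff(1:3, rep(TRUE, 3)), "non-empty")

  # accuracy always >= max class prevalence; equals exhaustive oracle
  set.seed(77)
  for (rep in 1:100) {
    n1 <- sample(3:12, 1L); n0 <- sample(3:12, 1L)
    sc <- c(rnorm(n1, 1), rnorm(n0))
    lb <- c(rep(TRUE, n1), rep(FALSE, n0))
    got <- roc_best_cutoff(sc, lb)
    oracle <- roc_bruteforce(sc, lb)
    expect_equal(got$accuracy, oracle$accuracy)
    expect_equal(got$sensitivity, oracle$sensitivity)
    expect_gte(got$accuracy, max(n1, n0) / (n1 + n0))
  }
})
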