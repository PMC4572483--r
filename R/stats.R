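# Group-level statistics: covariate-adjusted OLS with cluster-robust
# standard errors, interaction tests, correlations and effect sizes.

#' Cluster-robust (CR1) covariance for an lm fit
#'
#' Liang-Zeger sandwich estimator with the usual small-sample adjustment
#' m/(m-1) * (n-1)/(n-k), clustering observations (trials) within
#' participants.
#'
#' @param fit an `lm` object.
#' @param cluster vector of cluster ids, one per used observation.
#' @return covariance matrix of the coefficients.
#' @export
cluster_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  if (length(cluster) != nrow(X)) {
    stop("cluster vector length must match model rows (after NA omission)")
  }
  k <- ncol(X); n <- nrow(X)
  cl <- as.character(cluster)
  m <- length(unique(cl))
  Xu <- X * u
  meat_half <- rowsum(Xu, cl)
  meat <- crossprod(meat_half)
  bread <- solve(crossprod(X))
  adj <- m / (m - 1) * (n - 1) / (n - k)
  adj * bread %*% meat %*% bread
}

#' Fit the per-metric group model
#'
#' Ordinary least squares of the (optionally square-root transformed) metric
#' on group plus covariates -- always age, plus any of eccentricity,
#' condition (gap/overlap), axis, saccade amplitude as the metric requires
#' -- with optional interaction terms; standard errors are clustered by
#' participant. Pairwise group contrasts are reported with t statistics on
#' m - 1 degrees of freedom (m = number of clusters).
#'
#' @param rows data.frame with columns `participant_id`, `group`, `age`,
#'   `value`, plus any covariate columns named in `covariates`.
#' @param covariates character vector of additional regressors
#'   (default `"age"`).
#' @param interactions character vector of `a:b` interaction terms.
#' @param transform `"none"` or `"sqrt"`.
#' @return list: `fit`, `vcov`, `contrasts` (data.frame of pairwise group
#'   differences with SE, t, p), `df`.
#' @export
fit_group_model <- function(rows, covariates = "age", interactions = character(0),
                            transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  rows <- rows[!is.na(rows$value), , drop = FALSE]
  rows$group <- factor(rows$group)
  if (nlevels(rows$group) < 2L) stop("need at least 2 groups")
  cnt <- table(rows$group)
  if (any(cnt < 3L)) stop("each group needs n >= 3, got: ",
                          paste(names(cnt)[cnt < 3], collapse = ", "))
  rows$.y <- if (transform == "sqrt") sqrt(rows$value) else rows$value
  rhs <- c("group", covariates, interactions)
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = rows)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ", paste(bad, collapse = ", "))
  }
  used <- rownames(stats::model.matrix(fit))
  cl <- rows[used, "participant_id"]
  V <- cluster_vcov(fit, cl)
  df <- length(unique(cl)) - 1L
  list(fit = fit, vcov = V,
       contrasts = pairwise_group_contrasts(fit, V, df),
       df = df)
}

#' Pairwise group contrasts from a fitted group model
#' @keywords internal
pairwise_group_contrasts <- function(fit, V, df) {
  b <- stats::coef(fit)
  lv <- levels(fit$model$group)
  coef_of <- function(g) {
    nm <- paste0("group", g)
    v <- rep(0, length(b)); names(v) <- names(b)
    if (nm %in% names(b)) v[nm] <- 1
    v
  }
  pairs <- utils::combn(lv, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    cvec <- coef_of(g2) - coef_of(g1)
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tv <- est / se
    data.frame(contrast = paste(g2, "-", g1), estimate = est, se = se,
               t = tv, p = 2 * stats::pt(-abs(tv), df))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group-by-factor interaction test
#'
#' Adds a `group:factor` interaction to the group model and tests the
#' interaction coefficients jointly (Wald chi-square on the cluster-robust
#' covariance); also reports post hoc pairwise interaction contrasts for a
#' two-level factor.
#'
#' @param rows data.frame as in [fit_group_model()] with the factor column.
#' @param factor_name column to interact with group (e.g. `"condition"`).
#' @param covariates additional regressors (default `"age"`).
#' @param transform `"none"` or `"sqrt"`.
#' @return list: `fit`, `wald` (statistic, df, p), `pairwise` (data.frame of
#'   group-pair interaction contrasts, two-level factors only).
#' @export
interaction_test <- function(rows, factor_name, covariates = "age",
                             transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  rows <- rows[!is.na(rows$value), , drop = FALSE]
  rows$group <- factor(rows$group)
  rows[[factor_name]] <- factor(rows[[factor_name]])
  cells <- table(rows$group, rows[[factor_name]])
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("empty cell: group ", rownames(cells)[idx[1L]], " x ",
         factor_name, " ", colnames(cells)[idx[2L]])
  }
  rows$.y <- if (transform == "sqrt") sqrt(rows$value) else rows$value
  fml <- stats::as.formula(paste(
    ".y ~ group *", factor_name,
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- stats::lm(fml, data = rows)
  used <- rownames(stats::model.matrix(fit))
  cl <- rows[used, "participant_id"]
  V <- cluster_vcov(fit, cl)
  b <- stats::coef(fit)
  ia <- grep(paste0("^group.*:", factor_name), names(b))
  if (!length(ia)) ia <- grep(":", names(b), fixed = TRUE)
  W <- drop(t(b[ia]) %*% solve(V[ia, ia, drop = FALSE]) %*% b[ia])
  wald <- list(statistic = W, df = length(ia),
               p = stats::pchisq(W, length(ia), lower.tail = FALSE))
  # pairwise interaction contrasts (difference-in-differences) for 2-level factors
  pairwise <- NULL
  if (nlevels(rows[[factor_name]]) == 2L) {
    lv <- levels(rows$group)
    f2 <- levels(rows[[factor_name]])[2L]
    nm_of <- function(g) paste0("group", g, ":", factor_name, f2)
    df_cl <- length(unique(cl)) - 1L
    pairs <- utils::combn(lv, 2L)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
      cvec <- rep(0, length(b)); names(cvec) <- names(b)
      if (nm_of(g2) %in% names(b)) cvec[nm_of(g2)] <- 1
      if (nm_of(g1) %in% names(b)) cvec[nm_of(g1)] <- cvec[nm_of(g1)] - 1
      est <- sum(cvec * b)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      tv <- est / se
      data.frame(contrast = paste(g2, "-", g1), estimate = est, se = se,
                 t = tv, p = 2 * stats::pt(-abs(tv), df_cl))
    }))
    rownames(pairwise) <- NULL
  }
  list(fit = fit, vcov = V, wald = wald, pairwise = pairwise)
}

#' Pearson pairwise correlations with Bonferroni correction
#'
#' One correlation per (metric, score) column pair; the Bonferroni factor is
#' the number of tests in the family (all pairs by default).
#'
#' @param metrics data.frame of oculomotor metric columns (one row per
#'   participant).
#' @param scores data.frame of test-score columns, same rows.
#' @param family_size Bonferroni divisor; default `ncol(metrics) * ncol(scores)`.
#' @return list of matrices `r`, `p`, `p_bonferroni` (capped at 1), `n`,
#'   plus `n_tests`.
#' @export
pairwise_correlations <- function(metrics, scores, family_size = NULL) {
  metrics <- as.data.frame(metrics); scores <- as.data.frame(scores)
  nm <- ncol(metrics); ns <- ncol(scores)
  if (is.null(family_size)) family_size <- nm * ns
  r <- p <- nmat <- matrix(NA_real_, nm, ns,
                           dimnames = list(names(metrics), names(scores)))
  for (i in seq_len(nm)) for (j in seq_len(ns)) {
    x <- metrics[[i]]; y <- scores[[j]]
    ok <- stats::complete.cases(x, y)
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 4L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(r = r, p = p, p_bonferroni = pmin(p * family_size, 1), n = nmat,
       n_tests = family_size)
}

#' Cohen's d between two groups
#'
#' Mean difference divided by the pooled (n-1) standard deviation.
#'
#' @param x,y numeric vectors (n >= 2 each).
#' @return standardized mean difference; `NA` when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("cohens_d: need n >= 2 per group")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Direction registry: which side of the control distribution is "worse"
#'
#' @return named character vector, `"higher"` or `"lower"` per metric.
#' @export
metric_directions <- function() {
  c(swj_count = "higher",
    intrusive_saccades = "higher",
    longest_fixation_ms = "lower",
    time_to_target_ms = "higher",
    latency_ms = "higher",
    amplitude_error_deg = "lower",   # more negative = more hypometric
    peak_velocity = "higher",
    n_saccades = "higher",
    pursuit_gain = "lower",
    pursuit_saccades = "higher")
}

#' Classify impairment against control performance
#'
#' A score is impaired when it lies strictly more than `n_sd` standard
#' deviations to the "worse" side of the healthy-control mean.
#'
#' @param values numeric scores.
#' @param control_mean,control_sd healthy-control reference statistics.
#' @param worse `"higher"` or `"lower"`.
#' @param n_sd threshold (default 2, strict).
#' @return logical vector (`NA` propagates).
#' @export
classify_impairment <- function(values, control_mean, control_sd,
                                worse = c("higher", "lower"), n_sd = 2) {
  worse <- match.arg(worse)
  if (!is.finite(control_mean) || !is.finite(control_sd)) {
    stop("control mean/SD unavailable")
  }
  if (worse == "higher") values > control_mean + n_sd * control_sd
  else values < control_mean - n_sd * control_sd
}

#' Proportion of participants impaired on more than one metric
#'
#' @param flags logical matrix, participants x metrics (`NA` = not impaired).
#' @return fraction with >= 2 impaired metrics (strict "> 1").
#' @export
multi_metric_impairment_rate <- function(flags) {
  flags[is.na(flags)] <- FALSE
  mean(rowSums(flags) > 1)
}

#' Accuracy-maximising ROC cut-off
#'
#' Sweeps all midpoints between adjacent sorted unique scores plus the two
#' infinite cut-offs, in both threshold directions, and returns the cut-off
#' that maximises accuracy (TP + TN) / n. Ties are broken in favour of
#' higher sensitivity.
#'
#' @param scores numeric vector.
#' @param labels logical or two-level vector; `positive` marks the positive
#'   class (e.g. PCA).
#' @param positive value of `labels` treated as positive.
#' @return list: `cutoff`, `direction` (`">"` means score > cutoff flags
#'   positive), `sensitivity`, `specificity`, `accuracy`.
#' @export
roc_best_cutoff <- function(scores, labels, positive = TRUE) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok] == positive
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) stop("roc_best_cutoff: both classes must be non-empty")
  u <- sort(unique(scores))
  cuts <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (dir in c(">", "<")) {
    for (cut in cuts) {
      pred <- if (dir == ">") scores > cut else scores < cut
      tp <- sum(pred & labels); tn <- sum(!pred & !labels)
      acc <- (tp + tn) / (P + N)
      sens <- tp / P; spec <- tn / N
      if (is.null(best) || acc > best$accuracy ||
          (acc == best$accuracy && sens > best$sensitivity)) {
        best <- list(cutoff = cut, direction = dir, sensitivity = sens,
                     specificity = spec, accuracy = acc)
      }
    }
  }
  best
}
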