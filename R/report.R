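# High-level analysis drivers: group-comparison report, impairment
# classification and ROC tables over a metric table.

#' Registry of per-metric model specifications
#'
#' Which covariates and transform each metric's group model uses: age
#' always; eccentricity and gap/overlap condition for saccade-task metrics;
#' saccade amplitude for peak velocity; pursuit axis for pursuit metrics;
#' square-root transform for the two timing metrics.
#'
#' @return data.frame with `metric`, `covariates` (comma string),
#'   `transform`.
#' @export
model_registry <- function() {
  data.frame(
    metric = c("swj_count", "intrusive_saccades", "longest_fixation_ms",
               "time_to_target_ms", "latency_ms", "amplitude_error_deg",
               "peak_velocity", "n_saccades", "pursuit_gain",
               "pursuit_saccades"),
    covariates = c("age", "age", "age",
                   "age,eccentricity,condition", "age,eccentricity,condition",
                   "age,eccentricity,condition",
                   "age,eccentricity,condition,saccade_amplitude",
                   "age,eccentricity,condition", "age,axis", "age,axis"),
    transform = c("none", "none", "none", "sqrt", "sqrt", "none", "none",
                  "none", "none", "none"))
}

#' Group-comparison report over all metrics
#'
#' For each metric in the registry present in `rows`, fits the group model
#' with its registered covariates/transform (timing metrics are trimmed at
#' +/- 2 group SD on the transformed scale first) and collects the pairwise
#' group contrasts.
#'
#' @param rows long metric table from [compute_metrics()].
#' @param cfg configuration.
#' @return data.frame of contrasts with columns `metric`, `contrast`,
#'   `estimate`, `se`, `t`, `p`.
#' @export
group_report <- function(rows, cfg = default_config()) {
  reg <- model_registry()
  out <- list()
  for (i in seq_len(nrow(reg))) {
    m <- reg$metric[i]
    d <- rows[rows$metric == m & !is.na(rows$value), , drop = FALSE]
    if (!nrow(d)) next
    covs <- strsplit(reg$covariates[i], ",")[[1L]]
    covs <- covs[vapply(covs, function(cv) {
      cv %in% names(d) && length(unique(stats::na.omit(d[[cv]]))) > 1L
    }, logical(1L))]
    tf <- reg$transform[i]
    if (tf == "sqrt") {
      tr <- sqrt_transform_trim(d$value, d$group, z_max = cfg$trim_z)
      d <- d[tr$keep, , drop = FALSE]
      d$value <- tr$transformed[tr$keep]
      tf <- "none"  # already transformed
    }
    fit <- try(fit_group_model(d, covariates = covs, transform = tf),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    ct <- fit$contrasts
    ct$metric <- m
    out[[length(out) + 1L]] <- ct[, c("metric", "contrast", "estimate",
                                      "se", "t", "p")]
  }
  do.call(rbind, out)
}

#' Impairment flags and multi-metric impairment rates
#'
#' Classifies every participant against the healthy-control mean/SD per
#' metric (> 2 SD on the "worse" side, strict) and reports the proportion
#' per group impaired on more than one saccadic metric.
#'
#' @param summaries participant-level table from [participant_summaries()].
#' @param control_group label of the reference group.
#' @param family metrics constituting the saccadic family for the
#'   multi-metric rate.
#' @param n_sd threshold (default 2).
#' @return list: `flags` (logical matrix participants x metrics),
#'   `rates` (data.frame group, n, rate), `control_stats`.
#' @export
impairment_report <- function(summaries, control_group = "control",
                              family = c("time_to_target_ms", "latency_ms",
                                         "amplitude_error_deg", "n_saccades"),
                              n_sd = 2) {
  dirs <- metric_directions()
  metrics <- intersect(names(dirs), names(summaries))
  ctrl <- summaries[summaries$group == control_group, , drop = FALSE]
  if (!nrow(ctrl)) stop("no participants in control group '", control_group, "'")
  stats_tab <- data.frame(metric = metrics,
                          mean = vapply(metrics, function(m) mean(ctrl[[m]], na.rm = TRUE), numeric(1L)),
                          sd = vapply(metrics, function(m) stats::sd(ctrl[[m]], na.rm = TRUE), numeric(1L)))
  flags <- sapply(metrics, function(m) {
    classify_impairment(summaries[[m]], stats_tab$mean[stats_tab$metric == m],
                        stats_tab$sd[stats_tab$metric == m],
                        worse = dirs[[m]], n_sd = n_sd)
  })
  rownames(flags) <- summaries$participant_id
  fam <- intersect(family, colnames(flags))
  rates <- do.call(rbind, lapply(split(seq_len(nrow(summaries)), summaries$group),
    function(idx) {
      data.frame(group = summaries$group[idx[1L]], n = length(idx),
                 rate = multi_metric_impairment_rate(flags[idx, fam, drop = FALSE]))
    }))
  rownames(rates) <- NULL
  list(flags = flags, rates = rates, control_stats = stats_tab)
}

#' ROC table: accuracy-maximising cut-off per metric
#'
#' @param summaries participant-level table.
#' @param positive_group,negative_group the two classes (e.g. PCA vs tAD).
#' @return data.frame with one row per metric: cutoff, direction,
#'   sensitivity, specificity, accuracy.
#' @export
roc_report <- function(summaries, positive_group = "PCA",
                       negative_group = "tAD") {
  metrics <- intersect(names(metric_directions()), names(summaries))
  d <- summaries[summaries$group %in% c(positive_group, negative_group), ]
  out <- lapply(metrics, function(m) {
    ok <- !is.na(d[[m]])
    if (sum(ok & d$group == positive_group) < 1L ||
        sum(ok & d$group == negative_group) < 1L) return(NULL)
    r <- roc_best_cutoff(d[[m]][ok], d$group[ok] == positive_group)
    data.frame(metric = m, cutoff = r$cutoff, direction = r$direction,
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy)
  })
  do.call(rbind, out)
}
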