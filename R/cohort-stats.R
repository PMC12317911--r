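# Per-patient summaries, risk-group comparison, and ROC analysis of the
# imaging statistic alone, iPSA alone, and their logistic combination.

#' Summarize the water-to-oil ratio for one patient
#'
#' Runs the per-slice pipeline (ratio map, ROI masking, top-fraction
#' extraction) on each of the patient's slices, pools voxels across slices,
#' and reports the mean ratio over the full ROI and over the retained
#' brown-fat voxels.
#'
#' @param record a `PatientRecord` (see [generate_cohort()]): `patient_id`,
#'   `risk_group`, `ipsa`, and `slices`, each slice carrying `water`, `fat`
#'   and `mask`.
#' @param extraction an [extraction_spec()].
#' @param policy a [ratio_policy()].
#' @return a list of class `PatientSummary`: `patient_id`, `mean_rwo_full`,
#'   `mean_rwo_retained`, `n_elements_full`, `n_elements_retained`.
#' @export
summarize_patient <- function(record, extraction = extraction_spec(),
                              policy = ratio_policy()) {
  if (is.null(record$slices) || !length(record$slices))
    stop("patient record has no slices", call. = FALSE)
  full_vals <- numeric(0)
  retained_vals <- numeric(0)
  for (i in seq_along(record$slices)) {
    sl <- record$slices[[i]]
    if (!any(sl$mask$in_roi))
      stop(sprintf("patient %s slice %d has an empty ROI",
                   record$patient_id, i), call. = FALSE)
    r <- water_oil_ratio(sl$water, sl$fat, policy)
    pr <- apply_roi(r, sl$mask)
    ex <- extract_brown_fat(pr, sl$mask, extraction)
    full_vals <- c(full_vals, pr[sl$mask$in_roi])
    retained_vals <- c(retained_vals, ex$bprwo[ex$retained_indices])
  }
  structure(list(patient_id = record$patient_id,
                 mean_rwo_full = mean(full_vals),
                 mean_rwo_retained = mean(retained_vals),
                 n_elements_full = length(full_vals),
                 n_elements_retained = length(retained_vals)),
            class = "PatientSummary")
}

#' Compare a continuous measurement between two groups
#'
#' Computes a Welch two-sample t-test (pooled-variance optionally) with a
#' confidence interval for the mean difference, and a two-sided Mann-Whitney
#' test, matching the usual reporting for a continuous imaging biomarker
#' across clinical strata.
#'
#' @param values_a,values_b numeric vectors with at least 2 elements each.
#'   The reported difference is mean(a) - mean(b).
#' @param alpha significance level for the CI (default 0.05 for a 95% CI).
#' @param var_equal if `TRUE`, use the classic pooled-variance t-test instead
#'   of the Welch variant.
#' @return a list of class `GroupComparison` with the group means/SDs, the
#'   CI for the mean difference, and both p-values.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  tt <- tryCatch(
    stats::t.test(values_a, values_b, var.equal = var_equal,
                  conf.level = 1 - alpha),
    error = function(e) {
      if (!grepl("essentially constant", conditionMessage(e))) stop(e)
      # zero variance in both groups: the difference is exact, the t
      # procedure degenerates; report a width-zero interval and NA p-value
      d <- mean(values_a) - mean(values_b)
      list(conf.int = c(d, d), statistic = c(t = NaN), p.value = NA_real_)
    })
  mw <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  structure(list(mean_a = mean(values_a), mean_b = mean(values_b),
                 sd_a = stats::sd(values_a), sd_b = stats::sd(values_b),
                 difference = mean(values_a) - mean(values_b),
                 difference_ci_low = unname(tt$conf.int[1]),
                 difference_ci_high = unname(tt$conf.int[2]),
                 t_statistic = unname(tt$statistic),
                 t_p_value = tt$p.value,
                 mannwhitney_p_value = min(1, mw$p.value)),
            class = "GroupComparison")
}

# rank-based AUC (Mann-Whitney U / (n_pos * n_neg)); midranks give ties half
# credit. Fast path used by the bootstrap; roc_curve() reaches the same
# number via the threshold sweep and the two are cross-checked in tests.
auc_rank <- function(scores, labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' score >= threshold) to build the ROC curve from (0,0) to (1,1), and
#' integrates it by the trapezoid rule. Tied scores contribute diagonal
#' segments, so the area equals the Mann-Whitney concordance probability
#' with half credit for ties.
#'
#' @param scores numeric vector.
#' @param labels logical vector; `TRUE` marks the positive class. Both
#'   classes must be present.
#' @param feature_label optional name carried into reports.
#' @return a list of class `RocResult`: `auc`, `curve` (data.frame with
#'   `fpr`, `tpr`, `threshold`), `feature_label`, and `n_pos`/`n_neg`.
#' @export
roc_curve <- function(scores, labels, feature_label = "score") {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present for ROC analysis", call. = FALSE)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, 0)
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, thr))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1)
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, auc_sd = NA_real_, curve = curve,
                 feature_label = feature_label, n_pos = n_pos, n_neg = n_neg),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  sd_txt <- if (is.na(x$auc_sd)) "" else sprintf(" (SD %.3f)", x$auc_sd)
  cat(sprintf("<RocResult %s: AUC %.3f%s, %d pos / %d neg, %d curve points>\n",
              x$feature_label, x$auc, sd_txt, x$n_pos, x$n_neg, nrow(x$curve)))
  invisible(x)
}

#' Combine iPSA and the imaging statistic into one risk score
#'
#' Fits a maximum-likelihood logistic regression of the class labels on
#' (log iPSA, mean water-to-oil ratio) and returns the in-sample linear
#' predictor as the combined score. iPSA enters on the log scale because its
#' distribution is heavily right-skewed. Under perfect separation the
#' coefficients are not identifiable; the score ranking is still valid and
#' is returned with a warning and a `separation` attribute.
#'
#' @param ipsa positive iPSA values (ng/ml).
#' @param mean_rwo per-patient mean water-to-oil ratios.
#' @param labels logical class labels; both classes must be present.
#' @return numeric vector of linear-predictor scores, with attributes
#'   `coefficients` and `separation`.
#' @export
combine_features <- function(ipsa, mean_rwo, labels) {
  if (length(ipsa) != length(mean_rwo) || length(ipsa) != length(labels))
    stop("ipsa, mean_rwo and labels must have equal lengths", call. = FALSE)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  if (any(ipsa <= 0)) stop("ipsa values must be positive", call. = FALSE)
  df <- data.frame(y = labels, log_ipsa = log(ipsa), rwo = mean_rwo)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ log_ipsa + rwo, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated)
    warning("perfect or quasi-perfect separation: coefficients not identifiable, score ranking still valid",
            call. = FALSE)
  scores <- as.numeric(stats::predict(fit, type = "link"))
  attr(scores, "coefficients") <- stats::coef(fit)
  attr(scores, "separation") <- separated
  scores
}

#' Bootstrap uncertainty for an AUC
#'
#' Stratified nonparametric bootstrap: positives and negatives are resampled
#' with replacement within class (so every replicate keeps both classes), the
#' AUC is recomputed per replicate, and the SD plus the percentile 95% CI of
#' the replicate AUCs are returned.
#'
#' @param scores,labels as in [roc_curve()].
#' @param n_reps number of bootstrap replicates, at least 100 (default 2000).
#' @param seed integer seed.
#' @return a list with `auc_sd`, `ci_low`, `ci_high`, `n_reps`.
#' @export
bootstrap_auc <- function(scores, labels, n_reps = 2000L, seed = 1L) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  if (n_reps < 100L) stop("n_reps must be at least 100", call. = FALSE)
  pos <- which(labels); neg <- which(!labels)
  set.seed(as.integer(seed))
  aucs <- vapply(seq_len(n_reps), function(i) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    auc_rank(scores[idx], labels[idx])
  }, 0)
  qs <- unname(stats::quantile(aucs, c(0.025, 0.975), type = 7))
  list(auc_sd = stats::sd(aucs), ci_low = qs[1], ci_high = qs[2],
       n_reps = as.integer(n_reps))
}

#' Full cohort analysis report
#'
#' Summarizes every patient, compares the clinically-significant stratum
#' (high + intermediate risk) against the low-risk group on the per-patient
#' mean ratio, and runs three ROC analyses with high risk as the positive
#' class: the imaging statistic alone, iPSA alone, and their logistic
#' combination. Bootstrap SDs are attached to each AUC.
#'
#' @param cohort list of `PatientRecord` objects spanning at least 2 risk
#'   groups.
#' @param extraction an [extraction_spec()].
#' @param policy a [ratio_policy()].
#' @param roc_feature which per-patient mean feeds the ROC: the full-ROI
#'   mean (default) or the retained brown-fat mean.
#' @param n_boot bootstrap replicates per AUC (>= 100).
#' @param seed seed for the bootstrap.
#' @return a list of class `CohortReport`: `summaries` (data.frame),
#'   `group_stats` (data.frame), `comparison` (a `GroupComparison`,
#'   clinically-significant vs low), and `roc` (named list of `RocResult`
#'   for `rwo`, `ipsa`, `combined`).
#' @export
cohort_report <- function(cohort, extraction = extraction_spec(),
                          policy = ratio_policy(),
                          roc_feature = c("mean_rwo_full", "mean_rwo_retained"),
                          n_boot = 2000L, seed = 1L) {
  roc_feature <- match.arg(roc_feature)
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  groups <- vapply(cohort, `[[`, "", "risk_group")
  if (length(unique(groups)) < 2L)
    stop("cohort must span at least 2 risk groups", call. = FALSE)

  sums <- lapply(cohort, summarize_patient, extraction = extraction,
                 policy = policy)
  summaries <- data.frame(
    patient_id = vapply(sums, `[[`, "", "patient_id"),
    risk_group = groups,
    ipsa_ng_ml = vapply(cohort, `[[`, 0, "ipsa"),
    mean_rwo_full = vapply(sums, `[[`, 0, "mean_rwo_full"),
    mean_rwo_retained = vapply(sums, `[[`, 0, "mean_rwo_retained"),
    n_elements_full = vapply(sums, `[[`, 0, "n_elements_full"),
    n_elements_retained = vapply(sums, `[[`, 0, "n_elements_retained"),
    stringsAsFactors = FALSE)

  group_stats <- do.call(rbind, lapply(split(summaries, summaries$risk_group),
    function(g) data.frame(risk_group = g$risk_group[1], n = nrow(g),
                           mean_rwo = mean(g[[roc_feature]]),
                           sd_rwo = stats::sd(g[[roc_feature]]),
                           mean_ipsa = mean(g$ipsa_ng_ml),
                           sd_ipsa = stats::sd(g$ipsa_ng_ml),
                           stringsAsFactors = FALSE)))
  rownames(group_stats) <- NULL

  feature <- summaries[[roc_feature]]
  sig <- groups %in% c("high", "intermediate")
  if (!any(sig) || !any(groups == "low"))
    stop("clinically-significant vs low comparison needs both strata", call. = FALSE)
  comparison <- compare_groups(feature[sig], feature[groups == "low"])

  pos <- groups == "high"
  roc_rwo <- roc_curve(feature, pos, "mean_rwo")
  roc_ipsa <- roc_curve(summaries$ipsa_ng_ml, pos, "ipsa")
  combined <- suppressWarnings(
    combine_features(summaries$ipsa_ng_ml, feature, pos))
  roc_comb <- roc_curve(combined, pos, "combined")
  roc_rwo$auc_sd <- bootstrap_auc(feature, pos, n_boot, derive_seed(seed, 1L, 7L))$auc_sd
  roc_ipsa$auc_sd <- bootstrap_auc(summaries$ipsa_ng_ml, pos, n_boot,
                                   derive_seed(seed, 2L, 7L))$auc_sd
  roc_comb$auc_sd <- bootstrap_auc(combined, pos, n_boot,
                                   derive_seed(seed, 3L, 7L))$auc_sd

  structure(list(summaries = summaries, group_stats = group_stats,
                 comparison = comparison,
                 roc = list(rwo = roc_rwo, ipsa = roc_ipsa, combined = roc_comb),
                 roc_feature = roc_feature),
            class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("Cohort analysis report\n")
  cat(sprintf("  %d patients, groups: %s\n", nrow(x$summaries),
              paste(sprintf("%s (n=%d)", x$group_stats$risk_group,
                            x$group_stats$n), collapse = ", ")))
  cat(sprintf("  Clinically significant vs low %s: %.2f vs %.2f (95%% CI of difference %.2f to %.2f, t p=%.3g, MW p=%.3g)\n",
              x$roc_feature, x$comparison$mean_a, x$comparison$mean_b,
              x$comparison$difference_ci_low, x$comparison$difference_ci_high,
              x$comparison$t_p_value, x$comparison$mannwhitney_p_value))
  for (r in x$roc)
    cat(sprintf("  AUC (%s): %.3f (bootstrap SD %.3f)\n",
                r$feature_label, r$auc, r$auc_sd))
  invisible(x)
}
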