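# Patient summaries, group comparison, ROC machinery, feature combination,
# bootstrap uncertainty.

test_that("summarize_patient pools voxels across slices correctly", {
  mask <- roi_mask(matrix(TRUE, 6, 6))

  # constant in-ROI ratio c = 3: both means equal c
  rec <- manual_record(list(matrix(300L, 6, 6)), list(matrix(100L, 6, 6)), mask)
  s <- summarize_patient(rec)
  expect_equal(s$mean_rwo_full, 3)
  expect_equal(s$mean_rwo_retained, 3)
  expect_identical(s$n_elements_full, 36L)

  # two equal-size slices with full-ROI means 2 and 4 -> pooled mean 3
  rec2 <- manual_record(list(matrix(200L, 6, 6), matrix(400L, 6, 6)),
                        list(matrix(100L, 6, 6), matrix(100L, 6, 6)), mask)
  s2 <- summarize_patient(rec2)
  expect_equal(s2$mean_rwo_full, 3)
  expect_identical(s2$n_elements_full, 72L)

  # crafted slice: top 1% is 10x the rest; compare against loop recomputation
  h <- 20; w <- 50
  fat <- matrix(100L, h, w)
  water <- matrix(100L, h, w)
  set.seed(4)
  hot <- sample(h * w, 10)
  water[hot] <- 1000L
  mask3 <- roi_mask(matrix(TRUE, h, w))
  rec3 <- manual_record(list(water), list(fat), mask3)
  s3 <- summarize_patient(rec3)
  ratios <- as.numeric(water) / as.numeric(fat)
  k <- ceiling(0.01 * h * w)
  brute_retained <- mean(sort(ratios, decreasing = TRUE)[seq_len(k)])
  expect_equal(s3$mean_rwo_retained / s3$mean_rwo_full,
               brute_retained / mean(ratios))
  expect_identical(s3$n_elements_retained, as.integer(k))

  # empty-ROI slice is rejected naming the slice
  bad <- rec
  bad$slices[[1]]$mask <- roi_mask(matrix(FALSE, 6, 6))
  expect_error(summarize_patient(bad), "slice 1")
})

test_that("compare_groups matches the closed-form Welch statistic", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  cmp <- compare_groups(a, b)
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(cmp$t_statistic, t_hand)
  expect_equal(cmp$difference, -10)
  expect_lte(cmp$difference_ci_low, cmp$difference_ci_high)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$difference, 0)
  expect_lte(same$difference_ci_low, 0)
  expect_gte(same$difference_ci_high, 0)
  expect_equal(same$mannwhitney_p_value, 1)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("compare_groups is symmetric and consistent under a known shift", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(25, 1)
  ab <- compare_groups(x, y); ba <- compare_groups(y, x)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$difference_ci_low, -ba$difference_ci_high)
  expect_equal(ab$t_p_value, ba$t_p_value)
  expect_equal(ab$mannwhitney_p_value, ba$mannwhitney_p_value)

  # Monte-Carlo consistency: estimated difference within 3 SE of true shift
  set.seed(77)
  delta <- 0.6
  g1 <- rnorm(10000, delta, 1); g2 <- rnorm(10000, 0, 1)
  big <- compare_groups(g1, g2)
  se <- sqrt(2 / 10000)
  expect_lt(abs(big$difference - delta), 3 * se)
  expect_lt(big$t_p_value, 1e-10)
})

test_that("roc_curve agrees with brute-force concordance and behaves at the extremes", {
  perf <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perf$auc, 1.0)
  flat <- roc_curve(rep(2, 12), rep(c(TRUE, FALSE), 6))
  expect_equal(flat$auc, 0.5)

  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    scores <- sample(1:20, n, replace = TRUE)  # force ties
    labels <- runif(n) < 0.4
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, oracle_auc_concordance(scores, labels))
    # curve endpoints and monotonicity
    expect_equal(unlist(r$curve[1, 1:2]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), 1:2]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    # invariance under a strictly increasing transform
    r2 <- roc_curve(exp(scores / 5), labels)
    expect_equal(r2$auc, r$auc)
  }

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("combine_features behaves like logistic-regression scores should", {
  set.seed(15)
  n <- 60
  labels <- rep(c(TRUE, FALSE), n / 2)

  # constant imaging feature: combined AUC equals iPSA-alone AUC
  ipsa <- exp(rnorm(n, ifelse(labels, 2.5, 1.5), 0.7))
  sc <- combine_features(ipsa, rep(1, n), labels)
  expect_equal(roc_curve(sc, labels)$auc, roc_curve(ipsa, labels)$auc)

  # label determined by an ipsa threshold: separable, AUC 1, flagged
  ipsa2 <- exp(rnorm(n, 2, 1))
  lab2 <- ipsa2 > median(ipsa2)
  expect_warning(sc2 <- combine_features(ipsa2, rnorm(n), lab2), "separation")
  expect_true(attr(sc2, "separation"))
  expect_equal(roc_curve(sc2, lab2)$auc, 1.0)

  # binormal two-feature cohort: combined beats (or ties) each single feature
  for (seed in 1:5) {
    set.seed(100 + seed)
    lab <- runif(200) < 0.5
    f1 <- rnorm(200, ifelse(lab, 0.8, 0))
    f2 <- rnorm(200, ifelse(lab, 0.8, 0))
    sc3 <- suppressWarnings(combine_features(exp(f1), f2, lab))
    auc_c <- roc_curve(sc3, lab)$auc
    expect_gte(auc_c, roc_curve(f1, lab)$auc - 0.01)
    expect_gte(auc_c, roc_curve(f2, lab)$auc - 0.01)
  }

  expect_error(combine_features(1:3, 1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(combine_features(1:3, 1:2, c(TRUE, FALSE, TRUE)), "equal lengths")
})

test_that("bootstrap_auc is seeded, degenerate when separated, and rejects tiny reps", {
  set.seed(41)
  scores <- rnorm(40); labels <- rep(c(TRUE, FALSE), 20)
  b1 <- bootstrap_auc(scores, labels, n_reps = 300, seed = 9)
  b2 <- bootstrap_auc(scores, labels, n_reps = 300, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$ci_high)

  sep_scores <- c(rnorm(20, 10), rnorm(20, -10))
  sep_labels <- c(rep(TRUE, 20), rep(FALSE, 20))
  bs <- bootstrap_auc(sep_scores, sep_labels, n_reps = 300, seed = 3)
  expect_lt(bs$auc_sd, 0.01)
  expect_equal(bs$ci_high, 1.0)

  expect_error(bootstrap_auc(scores, labels, n_reps = 50), "at least 100")
})

test_that("bootstrap percentile CI covers a known binormal AUC", {
  # closed-form AUC for N(delta,1) vs N(0,1) is pnorm(delta / sqrt(2))
  delta <- 1
  true_auc <- pnorm(delta / sqrt(2))
  n <- 500
  covered <- 0L
  reps <- 200L
  set.seed(314)
  seeds <- sample.int(1e6, reps)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    scores <- c(rnorm(n, delta), rnorm(n))
    labels <- c(rep(TRUE, n), rep(FALSE, n))
    ci <- bootstrap_auc(scores, labels, n_reps = 200, seed = seeds[i])
    if (ci$ci_low <= true_auc && true_auc <= ci$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / reps, 0.90)
})

test_that("cohort_report assembles summaries, comparison and three ROCs", {
  cohort <- generate_cohort(params = tiny_params(), seed = 23)
  rep <- cohort_report(cohort, n_boot = 150, seed = 11)
  expect_identical(nrow(rep$summaries), 21L)
  expect_named(rep$roc, c("rwo", "ipsa", "combined"))
  for (r in rep$roc) {
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_false(is.na(r$auc_sd))
  }
  expect_identical(rep$roc$rwo$n_pos, 13L)

  # degenerate cohort: duplicated single patients per group -> group means
  # equal those patients' own summaries
  one_low <- cohort[[1]]; one_high <- cohort[[21]]
  stopifnot(one_low$risk_group == "low", one_high$risk_group == "high")
  dup <- list(one_low, one_low, one_high, one_high)
  rep2 <- cohort_report(dup, n_boot = 150, seed = 2)
  s_low <- summarize_patient(one_low)
  gs <- rep2$group_stats
  expect_equal(gs$mean_rwo[gs$risk_group == "low"], s_low$mean_rwo_full)

  # iPSA pure noise: combined AUC within the bootstrap CI of imaging alone
  noise <- lapply(cohort, function(r) { r$ipsa <- exp(rnorm(1, 2, 0.5)); r })
  set.seed(6)
  rep3 <- cohort_report(noise, n_boot = 300, seed = 6)
  feat <- rep3$summaries$mean_rwo_full
  pos <- rep3$summaries$risk_group == "high"
  ci <- bootstrap_auc(feat, pos, n_reps = 300, seed = 8)
  expect_gte(rep3$roc$combined$auc, ci$ci_low)
  expect_lte(rep3$roc$combined$auc, 1.0)

  expect_error(cohort_report(list(one_low, one_low)), "at least 2 risk groups")
})
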