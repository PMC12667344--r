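test_that("stratified folds balance both classes to within one record", {
  y <- rep(c(TRUE, FALSE), each = 10)
  f <- stratified_folds(y, 5, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab == 2))

  y <- rep(c(TRUE, FALSE), c(7, 13))
  f <- stratified_folds(y, 5, seed = 2)
  tab <- table(factor(f, 1:5), y)
  expect_true(all(tab[, "TRUE"] %in% 1:2))
  expect_true(all(tab[, "FALSE"] %in% 2:3))
  expect_equal(sum(tab), 20)

  expect_error(stratified_folds(rep(c(TRUE, FALSE), c(3, 20)), 5, seed = 1),
               "at least k")
  expect_identical(stratified_folds(y, 5, seed = 9),
                   stratified_folds(y, 5, seed = 9))
})

test_that("raw-ratio scoring is the identity and logistic scoring is monotone", {
  set.seed(13)
  cohort <- generate_cohort(sim_config(n_total = 300, seed = 55))$cohort
  r <- ratio(cohort$sflt1, cohort$plgf)

  raw <- cv_out_of_fold_scores(cohort, resampling_config(
    scoring_mode = "raw_ratio", seed = 1))
  expect_equal(as.numeric(raw), r)

  # a single in-sample logistic fit with positive slope preserves the
  # ratio ordering exactly
  y <- cohort$pe_within_14d
  s1 <- peratio:::.cv_scores(r, y, k = 1, scoring_mode = "logistic",
                             stratified = TRUE, seed = 1)
  expect_equal(order(s1), order(r))
  expect_equal(auc(as.numeric(s1), y), auc(r, y))
  # and the probability-scale Youden optimum maps to the raw-ratio optimum
  t_star <- youden_optimal_cutoff(as.numeric(s1), y)$cutoff
  expect_equal(min(r[s1 >= t_star]), youden_optimal_cutoff(r, y)$cutoff)

  # out-of-fold scores: every record scored once, fold-local monotonicity
  cfg <- resampling_config(seed = 4)
  s <- cv_out_of_fold_scores(cohort, cfg)
  expect_length(as.numeric(s), nrow(cohort))
  expect_equal(attr(s, "n_fallback"), 0L)
  expect_true(all(s >= 0 & s <= 1)) # probabilities, no fallback folds
  folds <- stratified_folds(y, cfg$k_folds, cfg$seed)
  for (fd in 1:5) {
    within <- folds == fd
    expect_equal(order(s[within]), order(r[within]))
  }
})

test_that("perfectly separated cohorts score AUC 1 in both modes", {
  cohort <- cohort_from_scores(c(1, 2, 3, 4, 5, 6, 50, 60, 70, 80, 90, 100),
                               rep(c(FALSE, TRUE), each = 6))
  for (mode in c("raw_ratio", "logistic")) {
    s <- cv_out_of_fold_scores(cohort, resampling_config(
      k_folds = 2, scoring_mode = mode, seed = 3))
    expect_equal(auc(as.numeric(s), cohort$pe_within_14d), 1)
  }
})

test_that("single-iteration bootstrap on a separable cohort finds the boundary", {
  cohort <- cohort_from_scores(c(2, 4, 6, 8, 10, 40, 55, 70, 85, 100),
                               rep(c(FALSE, TRUE), each = 5))
  for (mode in c("raw_ratio", "logistic")) {
    dist <- bootstrap_evaluate(cohort, resampling_config(
      k_folds = 2, n_bootstrap = 1, scoring_mode = mode, seed = 10))
    expect_equal(dist$iterations$auc, 1)
    # cutoff is the smallest PE-case ratio present in the replicate
    expect_true(dist$iterations$cutoff %in% c(40, 55, 70, 85, 100))
    expect_equal(dist$iterations$sensitivity, 1)
    expect_equal(dist$iterations$specificity, 1)
    # the no-resampling plug-in pass sees the full cohort boundary
    expect_equal(unname(dist$full_data["cutoff"]), 40)
    expect_equal(unname(dist$full_data["auc"]), 1)
  }
})

test_that("bootstrap evaluation is deterministic end-to-end under the seed", {
  cohort <- generate_cohort(sim_config(n_total = 150, seed = 66))$cohort
  cfg <- resampling_config(n_bootstrap = 25, seed = 12)
  d1 <- bootstrap_evaluate(cohort, cfg)
  d2 <- bootstrap_evaluate(cohort, cfg)
  expect_identical(d1$iterations, d2$iterations)
  expect_identical(summarize_bootstrap(d1), summarize_bootstrap(d2))
  d3 <- bootstrap_evaluate(cohort, resampling_config(n_bootstrap = 25, seed = 13))
  expect_false(identical(d1$iterations, d3$iterations))
})

test_that("the report summarizes percentile intervals and undefined counts", {
  # all-identical iterations collapse the CI onto the point
  cohort <- cohort_from_scores(c(rep(1, 6), rep(9, 6)),
                               rep(c(FALSE, TRUE), each = 6))
  rep1 <- evaluate_optimal_cutoff(cohort, resampling_config(
    k_folds = 2, n_bootstrap = 10, scoring_mode = "raw_ratio", seed = 1))
  auc_row <- rep1[rep1$metric == "auc", ]
  expect_equal(auc_row$ci_low, auc_row$estimate)
  expect_equal(auc_row$ci_high, auc_row$estimate)
  # with perfect specificity in every iteration LR+ is always undefined
  lr_row <- rep1[rep1$metric == "lr_pos", ]
  expect_true(is.na(lr_row$estimate))
  expect_equal(lr_row$n_undefined, 10)

  # percentile quantiles of a known dummy distribution
  dummy <- bootstrap_evaluate(cohort, resampling_config(
    k_folds = 2, n_bootstrap = 5, scoring_mode = "raw_ratio", seed = 2))
  set.seed(99)
  dummy$iterations <- data.frame(
    auc = runif(1000), cutoff = 1, sensitivity = 1, specificity = 1,
    ppv = 1, npv = 1, f1 = 1, lr_pos = NA_real_, lr_neg = 0,
    n_fallback = 0)
  dummy$full_data <- c(auc = 0.5, cutoff = 1, sensitivity = 1,
                       specificity = 1, ppv = 1, npv = 1, f1 = 1,
                       lr_pos = NA, lr_neg = 0, n_fallback = 0)
  rep2 <- summarize_bootstrap(dummy)
  auc_row <- rep2[rep2$metric == "auc", ]
  expect_lt(abs(auc_row$ci_low - 0.025), 0.015)
  expect_lt(abs(auc_row$ci_high - 0.975), 0.015)
  expect_lt(abs(auc_row$estimate - 0.5), 0.05)

  # report rows are exactly the nine reported parameters, in order
  expect_equal(rep2$metric,
               c("auc", "cutoff", "sensitivity", "specificity", "ppv",
                 "npv", "f1", "lr_pos", "lr_neg"))
})

test_that("bootstrap mean AUC tracks the generator's analytic ground truth", {
  # averaged over a few cohorts at study scale to separate pipeline bias
  # from single-cohort sampling noise
  cfg <- resampling_config(n_bootstrap = 60, seed = 5)
  aucs <- vapply(1:5, function(i) {
    sim <- generate_cohort(sim_config(n_total = 465, seed = 300 + i))
    d <- bootstrap_evaluate(sim$cohort, cfg)
    mean(d$iterations$auc)
  }, numeric(1))
  gt <- analytic_ground_truth(sim_config(n_total = 465, seed = 1))
  expect_equal(mean(aucs), unname(gt$auc["overall"]), tolerance = 0.02)
})

test_that("fixed-cutoff evaluation matches its definition and pairs with the optimum", {
  cohort <- generate_cohort(sim_config(n_total = 200, seed = 44))$cohort
  cfg <- resampling_config(n_bootstrap = 15, seed = 21)
  below <- evaluate_fixed_cutoff(cohort, 1e-6, cfg)
  expect_equal(below[below$metric == "sensitivity", "estimate"], 1)
  expect_equal(below[below$metric == "specificity", "estimate"], 0)
  expect_true(is.na(below[below$metric == "cutoff", "ci_low"]))
  expect_equal(below[below$metric == "cutoff", "estimate"], 1e-6)

  # separable cohort: fixing the cutoff at the boundary reproduces the
  # Youden-optimal report
  sep <- cohort_from_scores(c(1:6, 51:56), rep(c(FALSE, TRUE), each = 6))
  scfg <- resampling_config(k_folds = 2, n_bootstrap = 10,
                            scoring_mode = "raw_ratio", seed = 31)
  opt <- summarize_bootstrap(bootstrap_evaluate(sep, scfg))
  fix <- summarize_bootstrap(bootstrap_evaluate(sep, scfg, fixed_cutoff = 51))
  for (m in c("auc", "sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(fix[fix$metric == m, "estimate"],
                 opt[opt$metric == m, "estimate"])
  }
})

test_that("raising a cutoff across only false positives trades nothing for specificity", {
  # negatives at 40 and 45 sit between the cutoffs; positives all above 50
  scores <- c(5, 10, 20, 40, 45, 38, 50, 60, 70, 80, 90, 95)
  labels <- c(rep(FALSE, 6), rep(TRUE, 6))
  cohort <- cohort_from_scores(scores, labels)
  cfg <- resampling_config(k_folds = 2, n_bootstrap = 30,
                           scoring_mode = "raw_ratio", seed = 17)
  d33 <- bootstrap_evaluate(cohort, cfg, fixed_cutoff = 33)
  d50 <- bootstrap_evaluate(cohort, cfg, fixed_cutoff = 50)
  expect_equal(d33$iterations$sensitivity, d50$iterations$sensitivity)
  expect_true(all(d50$iterations$specificity >= d33$iterations$specificity))
  expect_gt(mean(d50$iterations$specificity), mean(d33$iterations$specificity))
})

test_that("median sensitivity CI width shrinks as the cohort grows", {
  cfg <- resampling_config(n_bootstrap = 60, seed = 8)
  median_width <- vapply(c(200, 2000), function(n) {
    widths <- vapply(1:8, function(i) {
      cohort <- generate_cohort(sim_config(n_total = n,
                                           seed = 1000 * i + n))$cohort
      r <- evaluate_optimal_cutoff(cohort, cfg)
      srow <- r[r$metric == "sensitivity", ]
      srow$ci_high - srow$ci_low
    }, numeric(1))
    median(widths)
  }, numeric(1))
  expect_lt(median_width[2], median_width[1])
})
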