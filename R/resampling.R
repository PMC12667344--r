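#' Resampling configuration
#'
#' Controls the estimation machinery: logistic-regression scoring of the
#' log sFlt-1/PlGF ratio under stratified k-fold cross-validation, nested
#' inside outcome-stratified bootstrap resampling. Defaults follow the
#' analysis design: 5 folds, 1000 bootstrap iterations, 95% percentile
#' confidence intervals.
#'
#' @param k_folds number of cross-validation folds (>= 2).
#' @param n_bootstrap bootstrap iterations (>= 1).
#' @param ci_level confidence level in (0, 1).
#' @param scoring_mode `"logistic"` (per-fold univariate logistic model on
#'   the log ratio, out-of-fold predicted probabilities as scores) or
#'   `"raw_ratio"` (the ratio itself, no fitting).
#' @param seed integer seed; every derived quantity is deterministic in it.
#' @param stratified stratify both the bootstrap resampling and the folds
#'   by outcome, preserving class counts (default `TRUE`).
#' @return a `resampling_config` list.
#' @export
resampling_config <- function(k_folds = 5, n_bootstrap = 1000,
                              ci_level = 0.95,
                              scoring_mode = c("logistic", "raw_ratio"),
                              seed, stratified = TRUE) {
  if (missing(seed)) stopf("resampling_config requires an explicit seed")
  scoring_mode <- match.arg(scoring_mode)
  if (k_folds < 2) stopf("k_folds must be >= 2")
  if (n_bootstrap < 1) stopf("n_bootstrap must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) stopf("ci_level must lie in (0, 1)")
  structure(
    list(k_folds = as.integer(k_folds),
         n_bootstrap = as.integer(n_bootstrap),
         ci_level = ci_level, scoring_mode = scoring_mode,
         seed = as.integer(seed), stratified = isTRUE(stratified)),
    class = "resampling_config"
  )
}

#' Stratified fold assignment
#'
#' Partitions records into `k` folds preserving the outcome-class balance:
#' within each class, fold sizes differ by at most one. Deterministic under
#' the seed.
#'
#' @param labels binary outcome per record.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..k) per record.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stopf("labels must be non-missing")
  n_by_class <- table(labels)
  if (length(n_by_class) < 2 || any(n_by_class < k)) {
    stopf("each outcome class needs at least k = %d members for stratified %d-fold CV",
          k, k)
  }
  with_seed(seed, {
    f <- integer(length(labels))
    for (cl in c(TRUE, FALSE)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    f
  })
}

# Fit a univariate logistic model P(PE | log ratio) on the training rows and
# return predicted probabilities for the test rows. Complete separation (or
# non-convergence) makes the fold fall back to raw-ratio scoring, flagged to
# the caller.
.logistic_fold_scores <- function(r_train, y_train, r_test) {
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, log(r_train)), as.numeric(y_train),
                   family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (warned || !fit$converged) {
    return(list(scores = r_test, fallback = TRUE))
  }
  eta <- cbind(1, log(r_test)) %*% fit$coefficients
  list(scores = as.numeric(stats::plogis(eta)), fallback = FALSE)
}

# Core scorer on plain vectors; k = 1 fits a single model on all records
# and scores them in-sample (used to check monotone equivalence with raw
# scoring).
.cv_scores <- function(r, y, k, scoring_mode, stratified, seed) {
  if (scoring_mode == "raw_ratio") {
    return(structure(r, n_fallback = 0L))
  }
  if (k == 1) {
    res <- .logistic_fold_scores(r, y, r)
    return(structure(res$scores, n_fallback = as.integer(res$fallback)))
  }
  folds <- if (stratified) {
    stratified_folds(y, k, seed)
  } else {
    with_seed(seed, sample(rep(seq_len(k), length.out = length(y))))
  }
  scores <- numeric(length(r))
  n_fallback <- 0L
  for (fd in seq_len(k)) {
    test <- folds == fd
    res <- .logistic_fold_scores(r[!test], y[!test], r[test])
    scores[test] <- res$scores
    if (res$fallback) n_fallback <- n_fallback + 1L
  }
  structure(scores, n_fallback = n_fallback)
}

#' Out-of-fold risk scores
#'
#' In logistic mode, for each fold a univariate logistic regression of the
#' outcome on the log sFlt-1/PlGF ratio is fit to the other k - 1 folds and
#' scores the held-out fold, so every record receives exactly one
#' out-of-fold predicted probability. In raw-ratio mode the scores are the
#' ratios themselves. A training split with complete separation falls back
#' to raw-ratio scoring for that fold; the number of such folds is attached
#' as the `n_fallback` attribute.
#'
#' @param cohort a [cohort_table] with both outcome classes.
#' @param config a [resampling_config()].
#' @return numeric score per record (attribute `n_fallback`).
#' @export
cv_out_of_fold_scores <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(config, "resampling_config"))
  r <- ratio(cohort$sflt1, cohort$plgf)
  y <- .check_scores_labels(r, cohort$pe_within_14d)
  .cv_scores(r, y, config$k_folds, config$scoring_mode, config$stratified,
             config$seed)
}

# One bootstrap replicate (or, with resample = FALSE, the full-data pass):
# resample stratified by outcome, score via CV, then either find the Youden
# optimum of the pooled out-of-fold scores or apply a fixed ratio cutoff.
.bootstrap_iteration <- function(r, y, config, iter_seed, fixed_cutoff = NULL,
                                 resample = TRUE) {
  idx <- if (resample) {
    with_seed(iter_seed, {
      if (config$stratified) {
        pos <- which(y); neg <- which(!y)
        c(pos[sample.int(length(pos), replace = TRUE)],
          neg[sample.int(length(neg), replace = TRUE)])
      } else {
        sample.int(length(y), replace = TRUE)
      }
    })
  } else {
    seq_along(y)
  }
  rb <- r[idx]; yb <- y[idx]
  if (!any(yb) || all(yb)) {
    return(NULL) # single-class resample (possible only unstratified)
  }
  scores <- .cv_scores(rb, yb, config$k_folds, config$scoring_mode,
                       config$stratified, derive_seed(iter_seed, 1))
  auc_b <- auc(scores, yb)
  if (is.null(fixed_cutoff)) {
    opt <- youden_optimal_cutoff(scores, yb)
    # Youden optimum lives on the score scale; report it on the ratio scale
    # as the smallest raw ratio among records the rule calls positive.
    cutoff_ratio <- if (config$scoring_mode == "logistic") {
      min(rb[scores >= opt$cutoff])
    } else {
      opt$cutoff
    }
    m <- opt$metrics
  } else {
    cutoff_ratio <- fixed_cutoff
    m <- metric_suite(confusion_at_cutoff(rb, yb, fixed_cutoff))
  }
  c(auc = auc_b, cutoff = cutoff_ratio,
    sensitivity = m$sensitivity, specificity = m$specificity,
    ppv = m$ppv, npv = m$npv, f1 = m$f1,
    lr_pos = m$lr_pos, lr_neg = m$lr_neg,
    n_fallback = as.numeric(attr(scores, "n_fallback")))
}

#' Bootstrap evaluation of cutoff performance
#'
#' The outer loop of the estimation machinery: in each of `n_bootstrap`
#' iterations the cohort is resampled with replacement stratified by
#' outcome (class sizes preserved, so every replicate and fold contains
#' both classes), out-of-fold scores are computed by stratified k-fold
#' cross-validated logistic scoring, the Youden-optimal cutoff of the
#' pooled scores is found and mapped to the ratio scale, and the full
#' metric suite at that cutoff is recorded. This yields one cutoff and one
#' metric set per iteration — the structure that supports a percentile
#' confidence interval on the optimal cutoff itself. With `fixed_cutoff`
#' the Youden step is skipped and the given ratio-scale cutoff is applied
#' in every iteration (AUC is still computed from the scores). A
#' no-resampling full-data pass is stored alongside as the plug-in
#' estimate. Deterministic under the config seed; two evaluations with the
#' same cohort, seed and iteration count are paired iteration-by-iteration
#' (see [z_test_paired_bootstrap()]).
#'
#' @param cohort a [cohort_table] with both outcome classes.
#' @param config a [resampling_config()].
#' @param fixed_cutoff optional fixed ratio cutoff; `NULL` (default) selects
#'   the Youden optimum per iteration.
#' @return a `bootstrap_distribution`: list with `iterations` (one row per
#'   bootstrap replicate), `full_data` (the plug-in pass), the config, seed
#'   and a cohort fingerprint used to enforce pairing.
#' @export
bootstrap_evaluate <- function(cohort, config, fixed_cutoff = NULL) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(config, "resampling_config"))
  r <- ratio(cohort$sflt1, cohort$plgf)
  y <- .check_scores_labels(r, cohort$pe_within_14d)
  rows <- vector("list", config$n_bootstrap)
  for (i in seq_len(config$n_bootstrap)) {
    rows[[i]] <- .bootstrap_iteration(r, y, config,
                                      derive_seed(config$seed, i),
                                      fixed_cutoff = fixed_cutoff)
  }
  dropped <- vapply(rows, is.null, logical(1))
  iterations <- as.data.frame(do.call(rbind, rows[!dropped]))
  full <- .bootstrap_iteration(r, y, config, derive_seed(config$seed, 0),
                               fixed_cutoff = fixed_cutoff, resample = FALSE)
  structure(
    list(
      iterations = iterations,
      full_data = full,
      n_dropped_single_class = sum(dropped),
      fixed_cutoff = fixed_cutoff,
      config = config,
      seed = config$seed,
      n = length(y),
      n_pos = sum(y),
      fingerprint = cohort_fingerprint(y, r)
    ),
    class = "bootstrap_distribution"
  )
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf(
    "Bootstrap distribution: %d iterations, n = %d (%d events)%s, seed %d\n",
    nrow(x$iterations), x$n, x$n_pos,
    if (!is.null(x$fixed_cutoff)) sprintf(", fixed cutoff %g", x$fixed_cutoff)
    else ", Youden-optimal cutoff", x$seed))
  invisible(x)
}

.report_metrics <- c("auc", "cutoff", "sensitivity", "specificity",
                     "ppv", "npv", "f1", "lr_pos", "lr_neg")

#' Summarize a bootstrap distribution into a performance report
#'
#' Point estimate = mean over the iterations where the metric is defined;
#' confidence interval = percentile interval of the same iterations at the
#' configured level. The full-data plug-in estimate is carried in its own
#' column, clearly separated from the bootstrap mean (for ratio-of-
#' proportion metrics such as LR+ the two can differ noticeably).
#' Iterations where a metric was undefined are skipped and counted, never
#' treated as zero. For a fixed-cutoff evaluation the cutoff row is the
#' fixed value with no interval.
#'
#' @param dist a [bootstrap_evaluate()] distribution.
#' @return a `performance_report` data.frame with one row per metric (AUC,
#'   optimal cutoff, sensitivity, specificity, PPV, NPV, F1, LR+, LR-) and
#'   columns `estimate`, `ci_low`, `ci_high`, `full_data`, `n_undefined`.
#' @export
summarize_bootstrap <- function(dist) {
  stopifnot(inherits(dist, "bootstrap_distribution"))
  if (!nrow(dist$iterations)) stopf("empty bootstrap distribution")
  level <- dist$config$ci_level
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(.report_metrics, function(m) {
    v <- dist$iterations[[m]]
    defined <- !is.na(v)
    if (m == "cutoff" && !is.null(dist$fixed_cutoff)) {
      return(data.frame(metric = m, estimate = dist$fixed_cutoff,
                        ci_low = NA_real_, ci_high = NA_real_,
                        full_data = dist$fixed_cutoff, n_undefined = 0L))
    }
    if (!any(defined)) {
      return(data.frame(metric = m, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_,
                        full_data = unname(dist$full_data[m]),
                        n_undefined = sum(!defined)))
    }
    q <- stats::quantile(v[defined], probs, names = FALSE)
    data.frame(metric = m, estimate = mean(v[defined]),
               ci_low = q[1], ci_high = q[2],
               full_data = unname(dist$full_data[m]),
               n_undefined = sum(!defined))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- dist$n
  attr(out, "n_pos") <- dist$n_pos
  attr(out, "prevalence") <- dist$n_pos / dist$n
  attr(out, "ci_level") <- level
  attr(out, "n_bootstrap") <- nrow(dist$iterations)
  attr(out, "seed") <- dist$seed
  attr(out, "scoring_mode") <- dist$config$scoring_mode
  attr(out, "fixed_cutoff") <- dist$fixed_cutoff
  class(out) <- c("performance_report", "data.frame")
  out
}

#' @export
print.performance_report <- function(x, ...) {
  fx <- attr(x, "fixed_cutoff")
  cat(sprintf(
    "Performance report (n = %d, %d events, prevalence %.1f%%, %d bootstrap iterations%s)\n",
    attr(x, "n"), attr(x, "n_pos"), 100 * attr(x, "prevalence"),
    attr(x, "n_bootstrap"),
    if (!is.null(fx)) sprintf(", fixed cutoff %g", fx) else ""))
  ci_pct <- 100 * attr(x, "ci_level")
  for (i in seq_len(nrow(x))) {
    ci <- if (is.na(x$ci_low[i])) "" else {
      sprintf(" (%.0f%% CI %.3g-%.3g)", ci_pct, x$ci_low[i], x$ci_high[i])
    }
    est <- if (is.na(x$estimate[i])) "undefined" else sprintf("%.3g", x$estimate[i])
    cat(sprintf("  %-12s %s%s\n", x$metric[i], est, ci))
  }
  invisible(x)
}

#' Evaluate the Youden-optimal cutoff with bootstrap confidence intervals
#'
#' Convenience wrapper: [bootstrap_evaluate()] followed by
#' [summarize_bootstrap()].
#' @inheritParams bootstrap_evaluate
#' @return a `performance_report`.
#' @export
evaluate_optimal_cutoff <- function(cohort, config) {
  summarize_bootstrap(bootstrap_evaluate(cohort, config))
}

#' Evaluate a fixed ratio cutoff with bootstrap confidence intervals
#'
#' Same resampling machinery as [evaluate_optimal_cutoff()] but the cutoff
#' is held fixed (no Youden step); with the same cohort and seed the two
#' evaluations are paired iteration-by-iteration, enabling
#' [z_test_paired_bootstrap()] comparisons between cutoffs.
#'
#' @inheritParams bootstrap_evaluate
#' @param cutoff the fixed ratio-scale cutoff (e.g. 33, 38 or 50).
#' @return a `performance_report` (no interval on the cutoff row).
#' @export
evaluate_fixed_cutoff <- function(cohort, cutoff, config) {
  summarize_bootstrap(bootstrap_evaluate(cohort, config, fixed_cutoff = cutoff))
}
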