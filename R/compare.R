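#' @title Statistical comparisons between groups and cutoffs
#' @description Two-sided tests used throughout the analysis: Z-tests
#' between performance metrics of two populations (unpaired) or two cutoffs
#' evaluated on the same cohort (paired by bootstrap iteration),
#' Mann-Whitney U for continuous characteristics and chi-square for
#' contingency tables. All p-values are two-sided and unadjusted.
#' @name group_comparison
NULL

comparison_result <- function(statistic, p_value, method, estimates = NULL,
                              details = NULL) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         estimates = estimates, details = details),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$estimates)) {
    cat("  estimates:", paste(sprintf("%.4g", unlist(x$estimates)),
                              collapse = " vs "), "\n")
  }
  invisible(x)
}

#' Unpaired Z-test between two metric estimates
#'
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2)` with a two-sided normal
#' p-value. Standard errors may be supplied directly or taken as the
#' standard deviation of a bootstrap distribution of the metric (see
#' [bootstrap_se()]).
#'
#' @param est1,est2 the two point estimates.
#' @param se1,se2 their standard errors, both > 0.
#' @return a `comparison_result` with method `"z_unpaired"`.
#' @examples
#' z_test_metrics(0.9, 0.05, 0.7, 0.05)
#' @export
z_test_metrics <- function(est1, se1, est2, se2) {
  if (any(c(se1, se2) <= 0) || any(is.na(c(se1, se2)))) {
    stopf("standard errors must be > 0")
  }
  z <- (est1 - est2) / sqrt(se1^2 + se2^2)
  comparison_result(
    statistic = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    method = "z_unpaired",
    estimates = list(est1 = est1, est2 = est2),
    details = list(se1 = se1, se2 = se2)
  )
}

#' Bootstrap standard error of a metric
#'
#' The standard deviation of the per-iteration bootstrap estimates, i.e.
#' the bootstrap estimate of the metric's sampling standard error.
#' @param dist a [bootstrap_evaluate()] distribution.
#' @param metric one of the report metrics (`"auc"`, `"cutoff"`,
#'   `"sensitivity"`, ...).
#' @return the standard error (undefined iterations skipped).
#' @export
bootstrap_se <- function(dist, metric) {
  stopifnot(inherits(dist, "bootstrap_distribution"))
  v <- dist$iterations[[metric]]
  if (is.null(v)) stopf("unknown metric '%s'", metric)
  stats::sd(v, na.rm = TRUE)
}

#' Paired Z-test between two bootstrap distributions
#'
#' For two evaluations of the *same* cohort under the same seed (e.g. two
#' fixed cutoffs), iterations are paired: the test operates on the
#' per-iteration differences, with `z = mean(diff) / sd(diff)` — the
#' bootstrap standard deviation of the difference *is* its standard error,
#' and pairing absorbs the between-iteration resampling variability shared
#' by both evaluations. Inputs with different iteration counts, seeds or
#' source cohorts are rejected.
#'
#' @param dist1,dist2 paired [bootstrap_evaluate()] distributions.
#' @param metric metric name to compare.
#' @return a `comparison_result` with method `"z_paired_bootstrap"`.
#' @export
z_test_paired_bootstrap <- function(dist1, dist2, metric) {
  stopifnot(inherits(dist1, "bootstrap_distribution"),
            inherits(dist2, "bootstrap_distribution"))
  if (nrow(dist1$iterations) != nrow(dist2$iterations) ||
      dist1$seed != dist2$seed ||
      !identical(dist1$fingerprint, dist2$fingerprint)) {
    stopf(paste("distributions are not paired: they must come from the same",
                "cohort, seed and iteration count"))
  }
  v1 <- dist1$iterations[[metric]]
  v2 <- dist2$iterations[[metric]]
  if (is.null(v1) || is.null(v2)) stopf("unknown metric '%s'", metric)
  ok <- !is.na(v1) & !is.na(v2)
  if (!any(ok)) stopf("metric '%s' undefined in every paired iteration", metric)
  d <- v1[ok] - v2[ok]
  sdd <- stats::sd(d)
  z <- if (sdd > 0) mean(d) / sdd else if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  comparison_result(
    statistic = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    method = "z_paired_bootstrap",
    estimates = list(est1 = mean(v1[ok]), est2 = mean(v2[ok])),
    details = list(mean_diff = mean(d), sd_diff = sdd, n_pairs = sum(ok),
                   n_dropped = sum(!ok))
  )
}

# Exhaustive two-sided Mann-Whitney p by enumerating all group-A index
# subsets; handles ties via midranks. Only called when choose(n, n_a) is
# small enough to enumerate.
.mw_exact_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mid <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  u_all <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
  p <- mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
  list(u = u_obs, p = p)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. Small samples (at most 20
#' per group) are handled exactly — by exhaustive enumeration of group
#' assignments when feasible (which is also correct under ties), otherwise
#' by the exact null distribution (tie-free data); larger samples use the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param values_a,values_b numeric samples, both non-empty.
#' @return a `comparison_result` with method `"mann_whitney"`; `statistic`
#'   is the U of the first sample, and `details` carries both U values
#'   (`u_a + u_b = n_a * n_b`) and which computation was used.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value # 1/3, exact
#' @export
mann_whitney <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stopf("both groups must be non-empty")
  na <- length(values_a); nb <- length(values_b)
  rk <- rank(c(values_a, values_b))
  u_a <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  small <- na <= 20 && nb <= 20
  if (small && choose(na + nb, na) <= 2e5) {
    res <- .mw_exact_enum(values_a, values_b)
    p <- res$p
    how <- "exact_enumeration"
  } else if (small && !ties) {
    p <- stats::wilcox.test(values_a, values_b, exact = TRUE)$p.value
    how <- "exact_distribution"
  } else {
    p <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                            correct = FALSE)$p.value
    how <- "normal_approximation"
  }
  comparison_result(
    statistic = u_a,
    p_value = p,
    method = "mann_whitney",
    estimates = list(median_a = stats::median(values_a),
                     median_b = stats::median(values_b)),
    details = list(u_a = u_a, u_b = na * nb - u_a, n_a = na, n_b = nb,
                   computation = how)
  )
}

#' Pearson chi-square test for a contingency table
#'
#' Pearson statistic without Yates continuity correction,
#' `df = (r - 1)(c - 1)`, p from the chi-square distribution.
#'
#' @param table an r x c matrix of non-negative counts (at least 2x2).
#' @return a `comparison_result` with method `"chi_square"`; `details`
#'   carries the degrees of freedom.
#' @examples
#' chi_square(matrix(c(10, 44, 35, 376), nrow = 2, byrow = TRUE))
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (!is.numeric(table) || any(is.na(table)) || any(table < 0)) {
    stopf("table must contain non-negative numeric counts")
  }
  if (nrow(table) < 2 || ncol(table) < 2) stopf("table must be at least 2x2")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  comparison_result(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = "chi_square",
    details = list(df = unname(ht$parameter))
  )
}
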