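#' sFlt-1/PlGF ratio
#'
#' Both concentrations are in pg/mL and must be strictly positive; the
#' ratio is dimensionless. High values indicate elevated short-term
#' preeclampsia risk.
#' @param sflt1,plgf serum concentrations (pg/mL), vectors of equal length.
#' @return `sflt1 / plgf`.
#' @examples
#' ratio(8960, 100)
#' @export
ratio <- function(sflt1, plgf) {
  if (length(sflt1) != length(plgf)) stopf("sflt1 and plgf differ in length")
  if (any(is.na(sflt1)) || any(is.na(plgf))) stopf("biomarker values missing")
  if (any(sflt1 <= 0) || any(plgf <= 0)) {
    stopf("biomarker concentrations must be > 0")
  }
  sflt1 / plgf
}

#' Confusion matrix at a cutoff
#'
#' Decision rule: a record is called positive when its score is greater
#' than or equal to the cutoff (published ratio thresholds such as 33, 38
#' and 50 are used boundary-inclusive as rule-in/rule-out values).
#'
#' @param scores numeric risk scores (typically sFlt-1/PlGF ratios).
#' @param labels binary outcomes (TRUE/1 = preeclampsia within 14 days).
#' @param cutoff decision threshold, same scale as `scores`.
#' @return a `confusion_matrix`: list with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- .check_scores_labels(scores, labels, both_classes = FALSE)
  call_pos <- scores >= cutoff
  structure(
    list(
      tp = sum(call_pos & labels), fp = sum(call_pos & !labels),
      tn = sum(!call_pos & !labels), fn = sum(!call_pos & labels)
    ),
    cutoff = cutoff,
    class = "confusion_matrix"
  )
}

.check_scores_labels <- function(scores, labels, both_classes = TRUE) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (length(scores) == 0) stopf("empty input")
  if (any(is.na(scores)) || any(is.na(labels))) stopf("missing scores or labels")
  labels <- as.logical(labels)
  if (both_classes && (!any(labels) || all(labels))) {
    stopf("both outcome classes must be present")
  }
  labels
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (cutoff %s): TP %d  FP %d  TN %d  FN %d\n",
              format(attr(x, "cutoff") %||% NA), x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Full metric suite from a confusion matrix
#'
#' Computes sensitivity, specificity, PPV, NPV, F1 score, the positive and
#' negative likelihood ratios, the Youden index J = sensitivity +
#' specificity - 1, and the empirical prevalence. A metric whose
#' denominator is zero (e.g. PPV with no positive calls, LR+ at perfect
#' specificity) is returned as `NA` — an explicit "undefined", never
#' coerced to 0 — so that bootstrap aggregation can skip and count it.
#'
#' @param cm a `confusion_matrix` from [confusion_at_cutoff()], or a list
#'   with fields `tp`, `fp`, `tn`, `fn`.
#' @return a `metric_set`: named list of the nine quantities above.
#' @examples
#' metric_suite(confusion_at_cutoff(c(10, 20, 40, 90), c(0, 0, 1, 1), 33))
#' @export
metric_suite <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  n <- tp + fp + tn + fn
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  lr_pos <- if (!is.na(sens) && !is.na(spec) && spec < 1) {
    sens / (1 - spec)
  } else NA_real_
  lr_neg <- if (!is.na(sens) && !is.na(spec) && spec > 0) {
    (1 - sens) / spec
  } else NA_real_
  structure(
    list(
      sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
      f1 = f1, lr_pos = lr_pos, lr_neg = lr_neg,
      youden_j = if (!is.na(sens) && !is.na(spec)) sens + spec - 1 else NA_real_,
      prevalence = div(tp + fn, n)
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x)
  cat("Metric set:\n")
  for (nm in names(v)) {
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(v[[nm]])) "undefined" else sprintf("%.4f", v[[nm]])))
  }
  invisible(x)
}

#' Predictive values at an assumed prevalence
#'
#' Bayes identities: `ppv = s*p / (s*p + (1-sp)*(1-p))` and
#' `npv = sp*(1-p) / (sp*(1-p) + (1-s)*p)`, with `s` sensitivity, `sp`
#' specificity, `p` prevalence. Useful for transporting test performance to
#' populations with different preeclampsia prevalence (PPV falls sharply in
#' low-prevalence settings).
#'
#' @param sensitivity,specificity,prevalence proportions in \[0, 1\].
#' @return list with `ppv` and `npv`; `NA` where a denominator is zero.
#' @examples
#' predictive_values_from_prevalence(0.938, 0.813, 0.097)
#' @export
predictive_values_from_prevalence <- function(sensitivity, specificity,
                                              prevalence) {
  vals <- c(sensitivity, specificity, prevalence)
  if (any(is.na(vals)) || any(vals < 0 | vals > 1)) {
    stopf("sensitivity, specificity and prevalence must lie in [0, 1]")
  }
  dp <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  dn <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  list(
    ppv = if (dp > 0) sensitivity * prevalence / dp else NA_real_,
    npv = if (dn > 0) specificity * (1 - prevalence) / dn else NA_real_
  )
}

#' Empirical ROC curve
#'
#' One point per distinct observed score (each a candidate cutoff under the
#' `score >= cutoff` rule) plus the degenerate all-negative endpoint
#' (fpr 0, tpr 0); the all-positive endpoint (1, 1) is reached at the
#' smallest observed score. Both tpr and fpr are non-decreasing along the
#' curve and each endpoint appears exactly once.
#'
#' @inheritParams confusion_at_cutoff
#' @return a `roc_curve`: data.frame with columns `cutoff`, `fpr`, `tpr`,
#'   ordered from the (0,0) to the (1,1) end.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  l_sorted <- labels[ord]
  tp_cum <- cumsum(l_sorted)
  fp_cum <- cumsum(!l_sorted)
  # last index of each distinct score block gives the counts at that cutoff
  blocks <- rle(scores[ord])
  idx <- cumsum(blocks$lengths)
  pts <- data.frame(
    cutoff = c(Inf, blocks$values),
    fpr = c(0, fp_cum[idx] / n_neg),
    tpr = c(0, tp_cum[idx] / n_pos)
  )
  structure(pts, class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the empirical ROC points; algebraically equal to
#' the Mann-Whitney pair statistic (#\{pos > neg\} + ties/2) / (n1 * n0).
#' 0.5 is chance discrimination, 1 perfect separation.
#'
#' @param scores numeric scores, or a `roc_curve` (then `labels` is omitted).
#' @inheritParams confusion_at_cutoff
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(1, 4, 3, 5), c(0, 0, 1, 1))
#' @export
auc <- function(scores, labels = NULL) {
  curve <- if (inherits(scores, "roc_curve")) scores else roc_curve(scores, labels)
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Youden-index optimal cutoff
#'
#' Scans the candidate cutoffs (the distinct observed scores, under the
#' `score >= cutoff` decision rule) and returns the one maximizing the
#' Youden index J = sensitivity + specificity - 1. Ties in J are broken
#' toward the smallest cutoff, which favours sensitivity and NPV — the
#' rule-out use of the ratio. With `midpoints = TRUE` the candidates are
#' the midpoints between consecutive distinct scores instead.
#'
#' @inheritParams confusion_at_cutoff
#' @param midpoints use midpoints between consecutive distinct scores as
#'   the candidate set (default `FALSE`: the observed scores themselves).
#' @return list with `cutoff` and `metrics` (the [metric_suite()] at it).
#' @examples
#' youden_optimal_cutoff(c(1, 2, 3, 2.5, 4, 5), c(0, 0, 0, 1, 1, 1))$cutoff
#' @export
youden_optimal_cutoff <- function(scores, labels, midpoints = FALSE) {
  labels <- .check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  ord <- order(scores)
  s_sorted <- scores[ord]
  cum_pos <- c(0, cumsum(labels[ord]))
  blocks <- rle(s_sorted)
  starts <- cumsum(blocks$lengths) - blocks$lengths + 1
  cand <- blocks$values
  # under the >= rule, at candidate v: positives called = those with score >= v
  sens <- (n_pos - cum_pos[starts]) / n_pos
  spec <- ((starts - 1) - cum_pos[starts]) / n_neg
  if (midpoints) {
    cand <- (utils::head(cand, -1) + utils::tail(cand, -1)) / 2
    sens <- utils::tail(sens, -1)
    spec <- utils::tail(spec, -1)
  }
  j <- sens + spec - 1
  best <- cand[which.max(j)] # which.max returns the first (smallest) maximizer
  list(
    cutoff = best,
    metrics = metric_suite(confusion_at_cutoff(scores, labels, best))
  )
}

#' Export ROC points as TSV
#'
#' @param curve a [roc_curve()].
#' @param path output path; columns `cutoff`, `tpr`, `fpr`.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.table(curve[, c("cutoff", "tpr", "fpr")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
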