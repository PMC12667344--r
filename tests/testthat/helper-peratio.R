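# Builders and independent brute-force oracles shared across tests.

# Minimal valid cohort whose sFlt-1/PlGF ratio equals the given scores
# (PlGF fixed at 1 pg/mL).
cohort_from_scores <- function(scores, labels, hypertensive = FALSE) {
  cohort_table(data.frame(
    patient_id = sprintf("T%04d", seq_along(scores)),
    hypertensive = rep_len(hypertensive, length(scores)),
    sflt1 = scores,
    plgf = 1,
    pe_within_14d = as.logical(labels),
    stringsAsFactors = FALSE
  ))
}

# Exhaustive per-record classification (oracle for confusion_at_cutoff).
bf_confusion <- function(scores, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pos_call <- scores[i] >= cutoff
    if (pos_call && labels[i]) tp <- tp + 1L
    if (pos_call && !labels[i]) fp <- fp + 1L
    if (!pos_call && !labels[i]) tn <- tn + 1L
    if (!pos_call && labels[i]) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Exhaustive pair enumeration (Mann-Whitney form of the AUC).
bf_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Brute-force Youden maximization over every distinct observed score,
# smallest cutoff on ties.
bf_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  best_j <- -Inf
  best_c <- NA_real_
  for (cu in cand) {
    sens <- sum(labels & scores >= cu) / sum(labels)
    spec <- sum(!labels & scores < cu) / sum(!labels)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- cu
    }
  }
  list(cutoff = best_c, j = best_j)
}

# Random two-class score instance.
random_instance <- function(n, tie_prone = FALSE) {
  labels <- c(TRUE, FALSE, runif(n - 2) < 0.4) # both classes guaranteed
  scores <- if (tie_prone) {
    sample(1:15, n, replace = TRUE) + ifelse(labels, 2, 0)
  } else {
    rnorm(n, mean = ifelse(labels, 1, 0))
  }
  list(scores = as.numeric(scores), labels = labels)
}
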