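#' @title Patient-level cohort tables
#' @description
#' A cohort table holds one row per enrolled participant: serum biomarker
#' concentrations (sFlt-1 and PlGF, pg/mL), hypertensive-disorder status at
#' enrollment, the binary outcome (preeclampsia diagnosed within 14 days of
#' the blood draw), eligibility-exclusion flags and optional baseline
#' covariates. `cohort_table()` validates a data.frame against the schema;
#' `read_cohort()` reads and validates a CSV.
#' @name cohort_table
NULL

# Canonical schema. `required` columns must resolve in any input; `flags`
# default to FALSE when absent; everything else is optional and kept as-is.
.cohort_required <- c("patient_id", "hypertensive", "sflt1", "plgf",
                      "pe_within_14d")
.cohort_flags <- c("excluded_prior_pe", "excluded_postpartum",
                   "excluded_missing_delivery")
.cohort_optional <- c("age", "ga_at_draw", "bmi_t1", "nulliparous",
                      "preterm_delivery", "c_section", "baby_weight",
                      "race", "smoker", "ga_at_delivery", "pe_ever")

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out[x == ""] <- NA
  out
}

#' Construct and validate a cohort table
#'
#' Checks the row-level invariants of the schema: biomarkers strictly
#' positive when present, logical outcome and exclusion flags, and for
#' eligible rows (no exclusion flag set) a non-missing outcome and, when
#' recorded, gestational age at draw of at least 20 weeks. Violations are
#' reported with the offending row and field rather than silently dropped.
#'
#' @param df a data.frame with at least the required columns
#'   (`patient_id`, `hypertensive`, `sflt1`, `plgf`, `pe_within_14d`);
#'   exclusion-flag columns default to `FALSE` when absent.
#' @return the validated data.frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_required, names(df))
  if (length(missing_cols)) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  for (fl in .cohort_flags) {
    df[[fl]] <- if (fl %in% names(df)) .as_flag(df[[fl]]) else FALSE
    df[[fl]][is.na(df[[fl]])] <- FALSE
  }
  df$hypertensive <- .as_flag(df$hypertensive)
  df$pe_within_14d <- .as_flag(df$pe_within_14d)
  df$patient_id <- as.character(df$patient_id)
  for (nm in c("sflt1", "plgf")) df[[nm]] <- as.numeric(df[[nm]])

  bad <- character(0)
  note <- function(rows, field, why) {
    if (length(rows)) {
      bad <<- c(bad, sprintf("row %d, field '%s': %s", rows, field, why))
    }
  }
  for (nm in c("sflt1", "plgf")) {
    note(which(!is.na(df[[nm]]) & df[[nm]] <= 0), nm, "must be > 0")
  }
  eligible <- !(df$excluded_prior_pe | df$excluded_postpartum |
                  df$excluded_missing_delivery)
  note(which(eligible & is.na(df$pe_within_14d)), "pe_within_14d",
       "outcome required for eligible records")
  note(which(is.na(df$hypertensive)), "hypertensive", "must be TRUE/FALSE")
  if ("ga_at_draw" %in% names(df)) {
    df$ga_at_draw <- as.numeric(df$ga_at_draw)
    note(which(eligible & !is.na(df$ga_at_draw) & df$ga_at_draw < 20),
         "ga_at_draw", "eligible records require GA >= 20 weeks")
  }
  if (length(bad)) {
    shown <- utils::head(bad, 10)
    stopf("cohort validation failed (%d violation%s):\n  %s%s",
          length(bad), if (length(bad) > 1) "s" else "",
          paste(shown, collapse = "\n  "),
          if (length(bad) > 10) "\n  ..." else "")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort CSV
#'
#' @param path CSV file (UTF-8, header row, empty cells as missing).
#' @param schema_options optional column-name mapping, either a named list /
#'   vector `canonical = "file column"` or the path of a YAML file whose
#'   `columns:` block holds that mapping.
#' @return a validated [cohort_table].
#' @examples
#' cohort <- generate_cohort(sim_config(n_total = 50, seed = 1))$cohort
#' f <- tempfile(fileext = ".csv")
#' write_cohort(cohort, f)
#' nrow(read_cohort(f))
#' @export
read_cohort <- function(path, schema_options = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.character(schema_options) && length(schema_options) == 1 &&
      file.exists(schema_options)) {
    schema_options <- yaml::read_yaml(schema_options)$columns
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(schema_options)) {
    mapping <- unlist(schema_options)
    for (canonical in names(mapping)) {
      src <- mapping[[canonical]]
      if (!src %in% names(df)) {
        stopf("mapped column '%s' (for '%s') not present in %s",
              src, canonical, path)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  cohort_table(df)
}

#' Write a cohort table to CSV
#'
#' Numeric fields are written at full precision (up to 15 significant
#' digits) so that a write/read round trip reproduces the table.
#' @param cohort a [cohort_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.15g", x))
  })
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply eligibility exclusions
#'
#' Removes participants diagnosed with preeclampsia before the blood draw,
#' those whose sample was collected postpartum, and those lacking delivery
#' information. A record carrying several flags is attributed to the first
#' applicable category in that order, so the logged counts are disjoint and
#' `n_eligible = n_enrolled - (n_prior_pe + n_postpartum + n_missing_delivery)`
#' holds exactly.
#'
#' @param cohort a [cohort_table] with exclusion flags.
#' @return a list with `cohort` (eligible rows, a [cohort_table]) and `log`
#'   (an `exclusion_log` with the five counts).
#' @examples
#' sim <- generate_enrollment_fixture(sim_config(
#'   n_total = 514, exclusion_counts = c(9, 25, 15), seed = 7))
#' apply_eligibility_filters(sim)$log
#' @export
apply_eligibility_filters <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  prior <- cohort$excluded_prior_pe
  postp <- !prior & cohort$excluded_postpartum
  missd <- !prior & !cohort$excluded_postpartum & cohort$excluded_missing_delivery
  eligible <- !(prior | postp | missd)
  log <- structure(
    list(
      n_enrolled = nrow(cohort),
      n_prior_pe = sum(prior),
      n_postpartum = sum(postp),
      n_missing_delivery = sum(missd),
      n_eligible = sum(eligible)
    ),
    class = "exclusion_log"
  )
  out <- cohort[eligible, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  list(cohort = out, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Eligibility exclusions\n")
  cat(sprintf("  enrolled:          %d\n", x$n_enrolled))
  cat(sprintf("  prior PE:          %d\n", x$n_prior_pe))
  cat(sprintf("  postpartum draw:   %d\n", x$n_postpartum))
  cat(sprintf("  missing delivery:  %d\n", x$n_missing_delivery))
  cat(sprintf("  eligible:          %d\n", x$n_eligible))
  invisible(x)
}

#' Percentage of a count over a denominator
#'
#' Reported to one decimal, rounding half away from zero (display
#' convention for clinical tables).
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return the percentage, one decimal.
#' @examples
#' proportion(54, 465) # 11.6
#' @export
proportion <- function(numerator, denominator) {
  if (any(denominator <= 0)) stopf("denominator must be > 0")
  if (any(numerator < 0 | numerator > denominator)) {
    stopf("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Baseline characteristics table
#'
#' Summarizes characteristics between exactly two groups, in the shape of a
#' clinical Table 1: continuous characteristics as median (IQR) per group
#' with a Mann-Whitney U p-value; categorical characteristics as n (%) per
#' level with chi-square p-values. For a characteristic with more than two
#' levels the p-value is computed per level on the 2x2 of that level versus
#' all others (without continuity correction); a logical characteristic gets
#' a single 2x2 p-value on its `TRUE` row. Percentages are computed over
#' non-missing records within each group.
#'
#' @param cohort a [cohort_table].
#' @param grouping name of a logical (or two-level) column, e.g.
#'   `"pe_within_14d"` or `"hypertensive"`.
#' @param characteristics character vector of column names; numeric columns
#'   are treated as continuous, everything else as categorical.
#' @return a `baseline_summary` data.frame with one row per characteristic
#'   (or per level), formatted group summaries, the raw numeric summaries,
#'   the p-value and the test used.
#' @export
baseline_table <- function(cohort, grouping, characteristics) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!grouping %in% names(cohort)) stopf("grouping column '%s' absent", grouping)
  g <- cohort[[grouping]]
  keep <- !is.na(g)
  g <- g[keep]
  cohort <- cohort[keep, , drop = FALSE]
  levs <- if (is.logical(g)) c(TRUE, FALSE) else sort(unique(g))
  if (length(unique(g)) != 2) stopf("grouping must yield exactly two groups")
  g1 <- g == levs[1]

  rows <- list()
  for (ch in characteristics) {
    if (!ch %in% names(cohort)) stopf("characteristic '%s' absent", ch)
    x <- cohort[[ch]]
    if (is.numeric(x)) {
      a <- x[g1 & !is.na(x)]
      b <- x[!g1 & !is.na(x)]
      p <- mann_whitney(a, b)$p_value
      qa <- stats::quantile(a, c(.25, .5, .75), names = FALSE)
      qb <- stats::quantile(b, c(.25, .5, .75), names = FALSE)
      fmt <- function(q) sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = ch, level = NA_character_, type = "continuous",
        group1 = fmt(qa), group2 = fmt(qb),
        g1_median = qa[2], g1_q1 = qa[1], g1_q3 = qa[3],
        g2_median = qb[2], g2_q1 = qb[1], g2_q3 = qb[3],
        g1_n = NA_integer_, g1_pct = NA_real_,
        g2_n = NA_integer_, g2_pct = NA_real_,
        p_value = p, test = "mann_whitney",
        stringsAsFactors = FALSE
      )
    } else {
      x <- if (is.logical(x)) factor(x, levels = c(TRUE, FALSE)) else factor(x)
      ok <- !is.na(x)
      n1 <- sum(g1 & ok); n2 <- sum(!g1 & ok)
      binary <- is.logical(cohort[[ch]])
      shown_levels <- if (binary) levels(x)[1] else levels(x)
      for (lv in shown_levels) {
        c1 <- sum(g1 & ok & x == lv); c2 <- sum(!g1 & ok & x == lv)
        tab <- matrix(c(c1, n1 - c1, c2, n2 - c2), nrow = 2)
        p <- tryCatch(chi_square(tab)$p_value, error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          characteristic = ch, level = as.character(lv), type = "categorical",
          group1 = sprintf("%d (%.1f)", c1, proportion(c1, max(n1, 1))),
          group2 = sprintf("%d (%.1f)", c2, proportion(c2, max(n2, 1))),
          g1_median = NA_real_, g1_q1 = NA_real_, g1_q3 = NA_real_,
          g2_median = NA_real_, g2_q1 = NA_real_, g2_q3 = NA_real_,
          g1_n = c1, g1_pct = proportion(c1, max(n1, 1)),
          g2_n = c2, g2_pct = proportion(c2, max(n2, 1)),
          p_value = p, test = "chi_square",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grouping") <- grouping
  attr(out, "group_levels") <- levs
  attr(out, "group_sizes") <- c(sum(g1), sum(!g1))
  class(out) <- c("baseline_summary", "data.frame")
  out
}

#' @export
print.baseline_summary <- function(x, ...) {
  levs <- attr(x, "group_levels")
  sizes <- attr(x, "group_sizes")
  cat(sprintf("Baseline characteristics by %s: %s (n = %d) vs %s (n = %d)\n\n",
              attr(x, "grouping"), levs[1], sizes[1], levs[2], sizes[2]))
  show <- data.frame(
    characteristic = ifelse(is.na(x$level), x$characteristic,
                            paste0(x$characteristic, ": ", x$level)),
    group1 = x$group1, group2 = x$group2,
    p = ifelse(is.na(x$p_value), "-",
               ifelse(x$p_value < 0.001, "<0.001", sprintf("%.3f", x$p_value))),
    test = x$test
  )
  print(show, row.names = FALSE)
  invisible(x)
}
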