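#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields accepted by [run_full_analysis()].
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s': %s", name, conditionMessage(e))
  })
}

.subgroup_rows <- function(cohort, subgroup) {
  switch(subgroup,
         all = rep(TRUE, nrow(cohort)),
         hypertensive = cohort$hypertensive,
         non_hypertensive = !cohort$hypertensive,
         stopf("unknown subgroup '%s'", subgroup))
}

.report_to_list <- function(report) {
  rows <- lapply(seq_len(nrow(report)), function(i) {
    list(metric = report$metric[i], estimate = report$estimate[i],
         ci_low = report$ci_low[i], ci_high = report$ci_high[i],
         full_data = report$full_data[i], n_undefined = report$n_undefined[i])
  })
  list(n = attr(report, "n"), n_pos = attr(report, "n_pos"),
       prevalence = attr(report, "prevalence"),
       ci_level = attr(report, "ci_level"),
       n_bootstrap = attr(report, "n_bootstrap"),
       scoring_mode = attr(report, "scoring_mode"),
       fixed_cutoff = attr(report, "fixed_cutoff"),
       metrics = rows)
}

.write_json <- function(x, path, provenance) {
  jsonlite::write_json(c(list(provenance = provenance), x), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Ties the modules into the complete workflow: load (or simulate) a
#' cohort, apply the eligibility exclusions, summarize baseline
#' characteristics, summarize the sFlt-1/PlGF ratio per stratum, evaluate
#' the Youden-optimal cutoff with bootstrap confidence intervals in the
#' requested subgroups, evaluate any fixed cutoffs, and compare subgroups
#' (unpaired Z on bootstrap standard errors) and cutoffs (paired Z by
#' bootstrap iteration). Every JSON artifact embeds the resolved
#' configuration hash and the master seed, so a re-run with the same
#' configuration is byte-identical. One master seed fans out to fixed
#' per-stage child seeds; within a subgroup the optimal-cutoff and
#' fixed-cutoff evaluations share a seed so they stay paired.
#'
#' @param config a list (or path of a YAML file) with fields:
#'   `out_dir` (required), `seed` (required), exactly one of `input` (cohort
#'   CSV path; optional `schema` column mapping) or `simulate` (arguments
#'   for [sim_config()], seed excluded), optional `subgroups` (default
#'   `c("all", "hypertensive")`), `fixed_cutoffs` (ratio values, default
#'   none), `baseline_characteristics`, and `resampling` (arguments for
#'   [resampling_config()], seed excluded).
#' @return invisibly, a list with the exclusion log, baseline table, ratio
#'   summaries, per-subgroup performance reports, comparison results and
#'   the paths written.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stopf("config requires 'out_dir'")
  if (is.null(config$seed)) stopf("config requires 'seed'")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stopf("config must provide exactly one input source: 'input' or 'simulate'")
  }
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subgroups <- config$subgroups %||% c("all", "hypertensive")
  fixed_cutoffs <- as.numeric(config$fixed_cutoffs %||% numeric(0))
  provenance <- list(
    package = "peratio",
    version = as.character(utils::packageVersion("peratio")),
    seed = seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")])
  )
  paths <- character(0)
  note <- function(fmt, ...) message(sprintf(paste0("[peratio] ", fmt), ...))

  enrolled <- .stage("load", {
    if (has_input) {
      read_cohort(config$input, schema_options = config$schema)
    } else {
      sim_args <- config$simulate
      sim_args$seed <- derive_seed(seed, 101)
      if (!is.null(sim_args$exclusion_counts)) {
        sim_args$exclusion_counts <- as.integer(unlist(sim_args$exclusion_counts))
      }
      cfg <- do.call(sim_config, sim_args)
      if (sum(cfg$exclusion_counts) > 0) {
        generate_enrollment_fixture(cfg)
      } else {
        generate_cohort(cfg)$cohort
      }
    }
  })
  note("load: %d records in", nrow(enrolled))

  filtered <- .stage("filter", apply_eligibility_filters(enrolled))
  cohort <- filtered$cohort
  excl <- filtered$log
  note("filter: %d in, %d eligible", excl$n_enrolled, excl$n_eligible)
  p <- file.path(out_dir, "exclusion_log.json")
  .write_json(unclass(excl), p, provenance); paths <- c(paths, p)
  p <- file.path(out_dir, "exclusion_log.tsv")
  .write_tsv(as.data.frame(unclass(excl)), p); paths <- c(paths, p)

  baseline <- .stage("baseline", {
    chars <- config$baseline_characteristics %||%
      intersect(c("age", "ga_at_draw", "bmi_t1", "nulliparous", "hypertensive"),
                names(cohort))
    baseline_table(cohort, "pe_within_14d", chars)
  })
  note("baseline: %d characteristic rows", nrow(baseline))
  p <- file.path(out_dir, "baseline_table.tsv")
  .write_tsv(as.data.frame(baseline), p); paths <- c(paths, p)

  ratio_summaries <- .stage("ratio_summary", {
    r <- ratio(cohort$sflt1, cohort$plgf)
    one <- function(label, keep) {
      q <- stats::quantile(r[keep], c(.25, .5, .75), names = FALSE)
      list(population = label, n = sum(keep),
           median = q[2], q1 = q[1], q3 = q[3])
    }
    sums <- list(one("overall", rep(TRUE, length(r))),
                 one("non_hypertensive", !cohort$hypertensive),
                 one("hypertensive", cohort$hypertensive))
    cmp <- mann_whitney(r[cohort$hypertensive], r[!cohort$hypertensive])
    list(summaries = sums,
         hypertensive_vs_non = list(p_value = cmp$p_value,
                                    method = cmp$method))
  })
  p <- file.path(out_dir, "ratio_summaries.json")
  .write_json(ratio_summaries, p, provenance); paths <- c(paths, p)

  resamp_args <- config$resampling %||% list()
  dists <- list(); reports <- list(); fixed_reports <- list()
  for (i in seq_along(subgroups)) {
    sg <- subgroups[[i]]
    keep <- .subgroup_rows(cohort, sg)
    sub <- cohort[keep, , drop = FALSE]
    class(sub) <- c("cohort_table", "data.frame")
    resamp_args$seed <- derive_seed(seed, 200 + i)
    rc <- do.call(resampling_config, resamp_args)
    dists[[sg]] <- .stage(paste0("evaluate:", sg), bootstrap_evaluate(sub, rc))
    reports[[sg]] <- summarize_bootstrap(dists[[sg]])
    note("evaluate %s: n = %d, %d events", sg, nrow(sub),
         sum(sub$pe_within_14d))
    p <- file.path(out_dir, sprintf("report_%s.json", sg))
    .write_json(.report_to_list(reports[[sg]]), p, provenance)
    paths <- c(paths, p)
    p <- file.path(out_dir, sprintf("report_%s.tsv", sg))
    .write_tsv(as.data.frame(reports[[sg]]), p); paths <- c(paths, p)
    for (cu in fixed_cutoffs) {
      key <- sprintf("%s_cutoff%g", sg, cu)
      fixed_reports[[key]] <- .stage(
        paste0("evaluate_fixed:", key),
        bootstrap_evaluate(sub, rc, fixed_cutoff = cu))
      rep_cu <- summarize_bootstrap(fixed_reports[[key]])
      p <- file.path(out_dir, sprintf("report_%s.json", key))
      .write_json(.report_to_list(rep_cu), p, provenance)
      paths <- c(paths, p)
    }
  }

  comparisons <- .stage("compare", {
    out <- list()
    if (all(c("all", "hypertensive") %in% names(dists))) {
      for (m in c("auc", "sensitivity", "specificity", "ppv", "npv")) {
        d1 <- dists[["all"]]; d2 <- dists[["hypertensive"]]
        v1 <- mean(d1$iterations[[m]], na.rm = TRUE)
        v2 <- mean(d2$iterations[[m]], na.rm = TRUE)
        ct <- z_test_metrics(v1, bootstrap_se(d1, m), v2, bootstrap_se(d2, m))
        out[[paste0("all_vs_hypertensive_", m)]] <-
          list(metric = m, method = ct$method, statistic = ct$statistic,
               p_value = ct$p_value, est_all = v1, est_hypertensive = v2)
      }
    }
    if (length(fixed_cutoffs) >= 2) {
      prs <- utils::combn(fixed_cutoffs, 2)
      for (sg in names(dists)) {
        for (jj in seq_len(ncol(prs))) {
          k1 <- sprintf("%s_cutoff%g", sg, prs[1, jj])
          k2 <- sprintf("%s_cutoff%g", sg, prs[2, jj])
          if (!k1 %in% names(fixed_reports)) next
          for (m in c("sensitivity", "specificity", "ppv", "npv")) {
            ct <- z_test_paired_bootstrap(fixed_reports[[k1]],
                                          fixed_reports[[k2]], m)
            out[[sprintf("%s_%g_vs_%g_%s", sg, prs[1, jj], prs[2, jj], m)]] <-
              list(metric = m, method = ct$method, statistic = ct$statistic,
                   p_value = ct$p_value,
                   est_1 = ct$estimates$est1, est_2 = ct$estimates$est2)
          }
        }
      }
    }
    out
  })
  p <- file.path(out_dir, "comparisons.json")
  .write_json(comparisons, p, provenance); paths <- c(paths, p)
  note("done: %d artifacts in %s", length(paths), out_dir)

  invisible(list(exclusion_log = excl, baseline = baseline,
                 ratio_summaries = ratio_summaries, reports = reports,
                 fixed_distributions = fixed_reports,
                 comparisons = comparisons, provenance = provenance,
                 paths = paths))
}
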