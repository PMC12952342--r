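# End-to-end orchestration: simulate or ingest a cohort, compute the score
# panel, run the association screen, the survival models (univariable +
# stage-adjusted), tertile analyses and cutpoint scans, and emit
# report tables shaped like the published association and Cox tables.

#' Tertile analysis of a metric against survival
#'
#' Cuts a metric at the cohort's 33.3rd and 66.7th mid-rank percentiles into
#' tertiles, fits a dummy-coded Cox model with tertile 1 (lowest) as the
#' reference, and computes Kaplan-Meier curves per tertile.
#'
#' @inheritParams km_estimate
#' @param x Metric values (>= 3 distinct).
#' @param metric_name Label for reporting.
#' @return A list with `tertile` (assignment 1-3 per tumor), `boundaries`
#'   (largest metric value in tertiles 1 and 2), `cox` (rows for tertile 2
#'   vs 1 and 3 vs 1), and `km` (per-tertile curves).
#' @export
tertile_analysis <- function(x, time, event, metric_name = "metric") {
  check_outcomes(time, event)
  if (any(is.na(x))) stop("metric values must not be missing")
  if (length(unique(x)) < 3) stop("at least 3 distinct metric values required")
  pct <- percentile_rank(x)
  tert <- 1L + (pct > 100 / 3) + (pct > 200 / 3)
  sizes <- tabulate(tert, nbins = 3)
  if (any(sizes == 0)) {
    empty <- which(sizes == 0)
    stop("ties collapse tertile ", paste(empty, collapse = ", "),
         " to empty at the ", paste(c("33.3", "66.7")[pmin(empty, 2)],
                                    collapse = "/"),
         " percentile boundary")
  }
  t2 <- as.integer(tert == 2L)
  t3 <- as.integer(tert == 3L)
  fit <- cox_fit(time, event, data.frame(tertile2_vs_1 = t2,
                                         tertile3_vs_1 = t3))
  km <- km_estimate(time, event, paste0("tertile_", tert))
  list(metric_name = metric_name,
       tertile = tert,
       boundaries = c(t1_max = max(x[tert == 1L]), t2_max = max(x[tert == 2L])),
       cox = fit,
       km = km)
}

pipeline_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[tilscore:%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

#' Run the full lymphocyte-scoring pipeline
#'
#' Orchestrates every stage: cohort acquisition (simulation via
#' [generate_cohort()] or an existing table/CSV, schema-checked), score panel,
#' distributional validation, association screen, univariable and
#' stage-adjusted Cox models for all panel metrics plus the optimal-cutpoint
#' dichotomies and I-score tertiles, tertile analyses (I-score and CD8+
#' density), and cutpoint scans with an optional permutation check. Given the
#' same input and seed the emitted tables are byte-identical.
#'
#' When the cohort has no events, the survival stages are skipped with an
#' explicit notice and the association screen still runs.
#'
#' @param config A [simulation_config()]; used when `cohort` is `NULL`.
#' @param cohort Optional cohort `data.frame` or path to a cohort CSV;
#'   exactly one input source is used (a supplied cohort takes precedence
#'   over simulation).
#' @param output_dir Optional directory; when given, all result tables are
#'   written there as CSV plus a `provenance.json`.
#' @param fdr_level FDR level for the association screen.
#' @param min_group_fraction Group-size floor for cutpoint scans.
#' @param cutpoint_metrics Metrics to scan for optimal cutoffs.
#' @param tertile_metrics Metrics for tertile analysis.
#' @param permutation_check If `TRUE`, run [permutation_minp_check()] for each
#'   scanned metric.
#' @param n_permutations Permutations for the check (default 199).
#' @param verbose Emit one structured log line per stage.
#' @return An object of class `til_run`: a list with `cohort`, `panel`,
#'   `validation`, `associations`, `cox_table` (one row per metric:
#'   univariable HR/CI/p and stage-adjusted HR/CI/p), `tertiles`,
#'   `cutpoints`, `notices`, and `provenance`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         cohort = NULL,
                         output_dir = NULL,
                         fdr_level = 0.05,
                         min_group_fraction = 0.10,
                         cutpoint_metrics = c("cd3_density", "cd8_density",
                                              "cd3_cov", "cd8_cov"),
                         tertile_metrics = c("iscore", "cd8_density"),
                         permutation_check = FALSE,
                         n_permutations = 199,
                         verbose = TRUE) {
  notices <- character(0)

  ## stage 1: cohort
  if (is.null(cohort)) {
    cohort_df <- generate_cohort(config)
    source_desc <- sprintf("simulated (n=%d, seed=%s)", config$n_patients,
                           format(config$seed))
  } else if (is.character(cohort)) {
    cohort_df <- read_cohort(cohort)
    source_desc <- paste("file:", cohort)
  } else {
    cohort_df <- cohort
    check_cohort_schema(cohort_df)
    source_desc <- "supplied data.frame"
  }
  pipeline_log(verbose, "cohort", "%s; %d tumors, %d events", source_desc,
               nrow(cohort_df), sum(cohort_df$dss_event))

  ## stage 2: score panel
  panel <- compute_panel(cohort_df)
  pipeline_log(verbose, "panel", "computed %d metrics per tumor",
               length(panel_metrics()))

  ## stage 3: distributional validation
  validation <- validate_cohort(cohort_df)
  pipeline_log(verbose, "validate", "%d checks, %d passed, %d flagged",
               nrow(validation), sum(validation$pass, na.rm = TRUE),
               sum(is.na(validation$pass)))

  ## stage 4: association screen
  associations <- run_association_screen(panel, fdr_level = fdr_level)
  pipeline_log(verbose, "associate", "%d tests on %d evaluable tumors (max)",
               nrow(associations$results), max(associations$results$n))

  ## stages 5-7: survival
  cox_table <- NULL
  tertiles <- NULL
  cutpoints <- NULL
  if (sum(cohort_df$dss_event) == 0) {
    notices <- c(notices,
                 "all outcomes censored: survival stages skipped")
    pipeline_log(verbose, "survive", "skipped: all outcomes censored")
  } else {
    time <- panel$followup_years
    event <- panel$dss_event

    cutpoints <- lapply(cutpoint_metrics, function(mt) {
      sc <- scan_cutpoints(panel[[mt]], time, event, min_group_fraction,
                           metric_name = mt)
      if (permutation_check) {
        sc$permutation <- permutation_minp_check(
          panel[[mt]], time, event, n_permutations,
          seed = config$seed, min_group_fraction = min_group_fraction)
      }
      sc
    })
    names(cutpoints) <- cutpoint_metrics
    pipeline_log(verbose, "cutpoint", "scanned %d metrics (floor %.0f%%)",
                 length(cutpoints), 100 * min_group_fraction)

    tertiles <- lapply(tertile_metrics, function(mt)
      tertile_analysis(panel[[mt]], time, event, metric_name = mt))
    names(tertiles) <- tertile_metrics
    pipeline_log(verbose, "tertile", "tertile models for %s",
                 paste(tertile_metrics, collapse = ", "))

    cox_table <- build_cox_table(panel, time, event, cutpoints, tertiles)
    pipeline_log(verbose, "survive", "%d metric rows, univariable + stage-adjusted",
                 nrow(cox_table))
  }

  provenance <- list(
    source = source_desc,
    n_patients = nrow(cohort_df),
    n_events = sum(cohort_df$dss_event),
    seed = if (is.null(cohort)) config$seed else attr(cohort_df, "til_config_seed"),
    fdr_level = fdr_level,
    min_group_fraction = min_group_fraction,
    package = "tilscore",
    version = as.character(utils::packageVersion("tilscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  result <- structure(list(cohort = cohort_df,
                           panel = panel,
                           validation = validation,
                           associations = associations,
                           cox_table = cox_table,
                           tertiles = tertiles,
                           cutpoints = cutpoints,
                           notices = notices,
                           provenance = provenance),
                      class = "til_run")
  if (!is.null(output_dir)) write_run(result, output_dir)
  result
}

# one row per metric of the published Cox-table layout: continuous metrics,
# optimal-cutoff dichotomies, and I-score tertile contrasts, each with the
# univariable and the jointly stage-adjusted HR
build_cox_table <- function(panel, time, event, cutpoints, tertiles) {
  rows <- list()
  add_metric <- function(label, values) {
    keep <- !is.na(values)
    uni <- cox_fit(time[keep], event[keep],
                   stats::setNames(data.frame(values[keep]), label))
    adj <- stage_adjusted_fit(time[keep], event[keep], values[keep],
                              panel$pt[keep], panel$pn[keep], panel$pm[keep],
                              metric_name = label)
    rows[[length(rows) + 1]] <<- data.frame(
      term = label,
      hr = uni$hr[1], ci_low = uni$ci_low[1], ci_high = uni$ci_high[1],
      p = uni$p[1],
      hr_adj = adj$hr[1], ci_low_adj = adj$ci_low[1],
      ci_high_adj = adj$ci_high[1], p_adj = adj$p[1])
  }

  for (marker in c("cd3", "cd8")) {
    add_metric(paste0(marker, "_density"), panel[[paste0(marker, "_density")]])
    add_metric(paste0(marker, "_pct"), panel[[paste0(marker, "_pct")]])
    add_metric(paste0(marker, "_cov"), panel[[paste0(marker, "_cov")]])
    cp <- cutpoints[[paste0(marker, "_density")]]
    if (!is.null(cp)) {
      add_metric(sprintf("%s_density_gt_%.0f", marker, cp$optimal_cutoff),
                 as.numeric(panel[[paste0(marker, "_density")]] >
                              cp$optimal_cutoff))
    }
  }
  add_metric("iscore", panel$iscore)
  tt <- tertiles[["iscore"]]
  if (!is.null(tt)) {
    add_metric("iscore_tertile2_vs_1", as.numeric(tt$tertile == 2))
    add_metric("iscore_tertile3_vs_1", as.numeric(tt$tertile == 3))
  }
  add_metric("diff_density", panel$diff_density)
  add_metric("diff_pct", panel$diff_pct)
  add_metric("ratio_density", panel$ratio_density)
  add_metric("ratio_pct", panel$ratio_pct)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# write all result tables; content is deterministic (no timestamps)
write_run <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(output_dir, name)
  utils::write.csv(result$panel, out("panel.csv"), row.names = FALSE)
  utils::write.csv(result$associations$results, out("associations.csv"),
                   row.names = FALSE)
  utils::write.csv(result$associations$group_summaries,
                   out("association_groups.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$validation), out("validation.csv"),
                   row.names = FALSE)
  if (!is.null(result$cox_table))
    utils::write.csv(result$cox_table, out("cox_models.csv"),
                     row.names = FALSE)
  if (!is.null(result$tertiles)) {
    tert_cox <- do.call(rbind, lapply(result$tertiles, function(tt) {
      df <- as.data.frame(tt$cox)
      df$metric <- tt$metric_name
      df
    }))
    utils::write.csv(tert_cox, out("tertiles_cox.csv"), row.names = FALSE)
    km_all <- do.call(rbind, lapply(result$tertiles, function(tt) {
      df <- as.data.frame(tt$km)
      df$metric <- tt$metric_name
      df
    }))
    utils::write.csv(km_all, out("km_curves.csv"), row.names = FALSE)
  }
  if (!is.null(result$cutpoints)) {
    for (mt in names(result$cutpoints)) {
      utils::write.csv(result$cutpoints[[mt]]$scan,
                       out(sprintf("cutpoint_scan_%s.csv", mt)),
                       row.names = FALSE)
    }
    summaries <- lapply(result$cutpoints, function(cp) {
      s <- cp[c("metric_name", "optimal_cutoff", "hr_at_cutoff", "ci_low",
                "ci_high", "p_at_cutoff", "percentile_of_cutoff", "n_low",
                "n_high")]
      if (!is.null(cp$permutation))
        s$p_permutation_adjusted <- cp$permutation$p_adjusted
      s
    })
    jsonlite::write_json(summaries, out("cutpoint_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  jsonlite::write_json(result$provenance, out("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.til_run <- function(x, ...) {
  cat("tilscore pipeline run —", x$provenance$source, "\n")
  cat(sprintf("  %d tumors, %d disease-specific deaths, %.0f person-years\n",
              x$provenance$n_patients, x$provenance$n_events,
              sum(x$cohort$followup_years)))
  cat("  validation:", sum(x$validation$pass, na.rm = TRUE), "of",
      nrow(x$validation), "distributional checks passed\n")
  if (!is.null(x$cox_table)) {
    cat("  Cox models (univariable + stage-adjusted):", nrow(x$cox_table),
        "metric rows\n")
  }
  for (nt in x$notices) cat("  notice:", nt, "\n")
  invisible(x)
}
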