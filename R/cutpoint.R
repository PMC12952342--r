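# Exhaustive minimal-p cutpoint search: dichotomize a continuous marker at
# every observed value, compute the two-group log-rank statistic for each
# split, and select the threshold with the smallest p. The log-rank trace is
# computed with a vectorized implementation of the hypergeometric O-E/V
# formula (identical to survival::survdiff) so that the permutation guard can
# re-run thousands of scans.

# Precomputed time-indexed matrices reused across permutations of the metric.
logrank_scan_setup <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  atrisk <- outer(ev_times, time, "<=")                    # K x n
  evmat <- outer(ev_times, time, "==") & rep(event == 1, each = length(ev_times))
  storage.mode(atrisk) <- "double"
  storage.mode(evmat) <- "double"
  ntot <- rowSums(atrisk)
  dtot <- rowSums(evmat)
  vfac <- ifelse(ntot > 1, dtot * (ntot - dtot) / (ntot - 1), 0)
  list(atrisk = atrisk, evmat = evmat, ntot = ntot, dtot = dtot, vfac = vfac)
}

# log-rank chi-square for every candidate split "x > v"; cand_idx are the
# group sizes n_low (positions in metric-sorted order).
logrank_scan_eval <- function(setup, x, cand_idx) {
  ord <- order(x)
  acum <- t(apply(setup$atrisk[, ord, drop = FALSE], 1, cumsum))
  dcum <- t(apply(setup$evmat[, ord, drop = FALSE], 1, cumsum))
  n1 <- acum[, cand_idx, drop = FALSE]                     # low group at risk
  o1 <- dcum[, cand_idx, drop = FALSE]
  frac <- n1 / setup$ntot
  e1 <- setup$dtot * frac
  v <- setup$vfac * frac * (1 - frac)
  u <- colSums(o1 - e1)
  vs <- colSums(v)
  chisq <- ifelse(vs > 0, u^2 / vs, NA_real_)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  list(chisq = chisq, p = p)
}

# candidate thresholds: each distinct observed value v (split "x > v") whose
# two groups both satisfy the size floor; returns values + n_low indices
scan_candidates <- function(x, min_group_fraction) {
  n <- length(x)
  xs <- sort(x)
  last_idx <- which(!duplicated(xs, fromLast = TRUE))  # n_low per distinct v
  values <- xs[last_idx]
  floor_n <- min_group_fraction * n
  keep <- last_idx >= floor_n & (n - last_idx) >= floor_n
  list(values = values[keep], n_low = last_idx[keep])
}

#' Exhaustive minimal-p survival cutpoint scan
#'
#' Dichotomizes a continuous metric at every distinct observed value `v`
#' (split: `metric > v` vs `<= v`), computes the two-group log-rank test for
#' each split whose groups both contain at least `min_group_fraction` of the
#' cohort, and selects the threshold with the smallest p value (ties broken
#' toward the smaller threshold). The optimal dichotomy's Cox hazard ratio
#' (high vs low, Efron ties) and the cutoff's mid-rank cohort percentile are
#' reported alongside the full scan trace.
#'
#' Because the threshold is chosen to minimize p, the reported
#' `p_at_cutoff` is optimistically biased; [permutation_minp_check()]
#' provides a selection-adjusted p value.
#'
#' @param x Continuous metric values (at least 2 distinct).
#' @param time,event Survival outcome (>= 1 event).
#' @param min_group_fraction Minimum fraction of the cohort in each group
#'   (default 0.10; must be in (0, 0.5)).
#' @param metric_name Label for reporting.
#' @return An object of class `til_cutpoint`: a list with `metric_name`,
#'   `optimal_cutoff`, `hr_at_cutoff`, `ci_low`, `ci_high`, `p_at_cutoff`
#'   (the minimal log-rank p), `percentile_of_cutoff`, `n_low`, `n_high`, and
#'   `scan` (a `data.frame`: `cutoff`, `n_low`, `n_high`, `chisq`, `p`).
#' @examples
#' cohort <- compute_panel(generate_cohort(simulation_config(n_patients = 80)))
#' scan_cutpoints(cohort$cd8_density, cohort$followup_years, cohort$dss_event,
#'                metric_name = "cd8_density")
#' @export
scan_cutpoints <- function(x, time, event, min_group_fraction = 0.10,
                           metric_name = "metric") {
  check_outcomes(time, event)
  if (length(x) != length(time)) stop("metric and outcome lengths differ")
  if (any(is.na(x))) stop("metric values must not be missing")
  if (length(unique(x)) < 2) stop("constant metric: no cutpoint exists")
  if (sum(event) < 1) stop("at least one event is required")
  if (min_group_fraction <= 0 || min_group_fraction >= 0.5)
    stop("min_group_fraction must lie in (0, 0.5)")

  cand <- scan_candidates(x, min_group_fraction)
  if (length(cand$values) == 0)
    stop("no candidate threshold satisfies the group-size floor")

  setup <- logrank_scan_setup(time, event)
  ev <- logrank_scan_eval(setup, x, cand$n_low)
  n <- length(x)
  scan <- data.frame(cutoff = cand$values,
                     n_low = cand$n_low,
                     n_high = n - cand$n_low,
                     chisq = ev$chisq,
                     p = ev$p)
  if (all(is.na(scan$p)))
    stop("log-rank statistic undefined at every candidate threshold")
  pmin_val <- min(scan$p, na.rm = TRUE)
  best <- which(!is.na(scan$p) & scan$p == pmin_val)
  best <- best[which.min(scan$cutoff[best])]  # tie -> smaller threshold
  cutoff <- scan$cutoff[best]

  high <- as.integer(x > cutoff)
  hr_fit <- cox_fit(time, event, data.frame(high = high))
  pct <- percentile_rank(x)
  structure(list(metric_name = metric_name,
                 optimal_cutoff = cutoff,
                 hr_at_cutoff = hr_fit$hr[1],
                 ci_low = hr_fit$ci_low[1],
                 ci_high = hr_fit$ci_high[1],
                 hr_p = hr_fit$p[1],
                 p_at_cutoff = scan$p[best],
                 percentile_of_cutoff = unique(pct[x == cutoff])[1],
                 n_low = scan$n_low[best],
                 n_high = scan$n_high[best],
                 min_group_fraction = min_group_fraction,
                 scan = scan),
            class = "til_cutpoint")
}

#' Permutation adjustment for minimal-p cutpoint selection
#'
#' Selecting the threshold that minimizes the log-rank p value inflates the
#' apparent significance. This check permutes the metric values against the
#' (fixed) survival outcomes, re-runs the full cutpoint scan on each
#' permutation, and returns the Monte Carlo p value
#' `(1 + #\{min-p_perm <= min-p_obs\}) / (1 + n_permutations)` — the
#' probability, under no metric-outcome association, of reaching a minimal p
#' at least as small by scanning alone.
#'
#' @inheritParams scan_cutpoints
#' @param n_permutations Number of permutations (>= 100; default 199).
#' @param seed Integer seed; the same seed gives an identical adjusted p.
#' @return A list with `p_adjusted`, `p_observed` (the observed minimal p),
#'   `n_permutations`, and `seed`.
#' @export
permutation_minp_check <- function(x, time, event, n_permutations = 199,
                                   seed = 1L, min_group_fraction = 0.10) {
  if (n_permutations < 100) stop("at least 100 permutations are required")
  observed <- scan_cutpoints(x, time, event, min_group_fraction)
  p_obs <- observed$p_at_cutoff

  cand <- scan_candidates(x, min_group_fraction)
  setup <- logrank_scan_setup(time, event)
  minp_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(b) {
      xp <- sample(x)
      ev <- logrank_scan_eval(setup, xp, cand$n_low)
      min(ev$p, na.rm = TRUE)
    }, numeric(1))
  })
  p_adj <- (1 + sum(minp_perm <= p_obs + 1e-12)) / (1 + n_permutations)
  list(p_adjusted = p_adj, p_observed = p_obs,
       n_permutations = n_permutations, seed = seed)
}

#' @export
print.til_cutpoint <- function(x, ...) {
  cat(sprintf("Optimal cutpoint for %s: > %.4g (%.0fth percentile)\n",
              x$metric_name, x$optimal_cutoff, x$percentile_of_cutoff))
  cat(sprintf("  log-rank p = %.3g; high-vs-low HR = %.3g [%.3g, %.3g]\n",
              x$p_at_cutoff, x$hr_at_cutoff, x$ci_low, x$ci_high))
  cat(sprintf("  groups: %d low / %d high; %d thresholds scanned (floor %.0f%%)\n",
              x$n_low, x$n_high, nrow(x$scan), 100 * x$min_group_fraction))
  invisible(x)
}
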