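# Disease-specific survival analysis: Kaplan-Meier, log-rank, and Cox
# proportional-hazards models (Efron ties) with joint pT/pN/pM stage
# adjustment. The survival package supplies the estimators; this module fixes
# the contracts (error states, result shapes) used by the rest of the
# pipeline.

check_outcomes <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(time <= 0)) stop("all times must be > 0")
  if (!all(event %in% 0:1)) stop("event must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator of disease-specific survival, by group. Tied event
#' times decrement the curve simultaneously. The returned step function
#' starts at 1 and is nonincreasing within each group.
#'
#' @param time Positive follow-up times (years).
#' @param event Binary event indicator (1 = death from disease).
#' @param group Optional grouping vector; default one combined curve.
#' @return A `data.frame` of class `til_km` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, including a `time = 0` anchor
#'   row per group.
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_outcomes(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  if (any(is.na(group))) stop("group labels must not be missing")
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("every group must be nonempty")

  out <- lapply(levels(group), function(g) {
    idx <- group == g
    fit <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    data.frame(group = g,
               time = c(0, fit$time),
               n_risk = c(sum(idx), fit$n.risk),
               n_event = c(0, fit$n.event),
               n_censor = c(0, fit$n.censor),
               surv = c(1, fit$surv))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("til_km", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square statistic (1 df)
#' comparing disease-specific survival between two groups. With zero events
#' the statistic is undefined and the result is flagged rather than an error.
#'
#' @inheritParams km_estimate
#' @param group Two-level grouping vector; both levels nonempty.
#' @return A list with `statistic`, `df` (1), `p`, per-group `observed` and
#'   `expected` event counts, and `note` when undefined.
#' @export
log_rank <- function(time, event, group) {
  check_outcomes(time, event)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (any(table(group) == 0)) stop("both groups must be nonempty")
  if (sum(event) == 0) {
    return(list(statistic = NA_real_, df = 1, p = NA_real_,
                observed = c(0, 0), expected = c(0, 0),
                note = "no events: log-rank statistic undefined"))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd_fit$chisq), df = 1,
       p = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd_fit$obs), expected = unname(sd_fit$exp),
       note = NULL)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization with Efron handling of
#' tied event times, and returns per-term hazard ratios with Wald confidence
#' intervals and p values. Explicit error states: no events, constant
#' covariate, collinear covariates, or non-convergence.
#'
#' @inheritParams km_estimate
#' @param covariates A numeric vector, matrix or `data.frame` of covariates.
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return A `data.frame` of class `til_cox` with one row per term: `term`,
#'   `coef` (log hazard ratio), `hr`, `ci_low`, `ci_high`, `se`, `z`, `p`.
#'   Attributes: `loglik` (at solution), `loglik_null`, `n`, `n_event`,
#'   `score_test` (the score chi-square at beta = 0).
#' @examples
#' cohort <- compute_panel(generate_cohort(simulation_config(n_patients = 120)))
#' cox_fit(cohort$followup_years, cohort$dss_event,
#'         data.frame(cd8_per100 = cohort$cd8_density / 100))
#' @export
cox_fit <- function(time, event, covariates, ties = "efron",
                    conf_level = 0.95) {
  check_outcomes(time, event)
  if (is.null(dim(covariates))) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  x <- as.matrix(covariates)
  if (!is.numeric(x)) stop("covariates must be numeric")
  keep <- complete.cases(x) & !is.na(time) & !is.na(event)
  x <- x[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (sum(event) < 1) stop("no events: Cox model cannot be fitted")
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    stop("constant covariate: ", paste(colnames(x)[const], collapse = ", "))
  if (qr(scale(x, scale = FALSE))$rank < ncol(x))
    stop("collinear covariates: design matrix is rank-deficient")

  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (any(is.na(fit$coefficients)))
    stop("Cox model did not converge to finite coefficients")
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = colnames(x),
                    coef = unname(beta),
                    hr = unname(exp(beta)),
                    ci_low = unname(exp(beta - zq * se)),
                    ci_high = unname(exp(beta + zq * se)),
                    se = unname(se),
                    z = unname(beta / se),
                    p = unname(2 * pnorm(-abs(beta / se))))
  rownames(out) <- NULL
  attr(out, "loglik") <- fit$loglik[2]
  attr(out, "loglik_null") <- fit$loglik[1]
  attr(out, "n") <- fit$n
  attr(out, "n_event") <- fit$nevent
  attr(out, "score_test") <- unname(fit$score)
  class(out) <- c("til_cox", "data.frame")
  out
}

#' Stage-adjusted Cox fit for a metric
#'
#' Assesses whether a lymphocyte metric carries prognostic information beyond
#' AJCC pathologic staging. The primary mode (`"joint"`) fits
#' `metric + pT + pN + pM` in one multivariable model and returns the
#' metric's hazard ratio from that model; `"individual"` adds each stage
#' stratum one at a time and returns the metric's row from each of the three
#' two-covariate models. pT and pN enter as ordinal integer scores and pM as
#' binary.
#'
#' @inheritParams km_estimate
#' @param metric Numeric metric values (continuous or dummy-coded).
#' @param pt,pn,pm Stage variables (pT 1-4, pN 0-2, pM 0/1).
#' @param mode `"joint"` (default) or `"individual"`.
#' @param metric_name Label used for the metric's row.
#' @return For `"joint"`: the metric's single-row `til_cox` result, with the
#'   full model attached as attribute `model`. For `"individual"`: a
#'   `data.frame` of the metric's row from each model, with column
#'   `adjusted_for`.
#' @export
stage_adjusted_fit <- function(time, event, metric, pt, pn, pm,
                               mode = c("joint", "individual"),
                               metric_name = "metric") {
  mode <- match.arg(mode)
  if (mode == "joint") {
    fit <- cox_fit(time, event,
                   stats::setNames(data.frame(metric, pt, pn, pm),
                                   c(metric_name, "pt", "pn", "pm")))
    out <- fit[fit$term == metric_name, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "model") <- fit
    return(out)
  }
  rows <- lapply(c("pt", "pn", "pm"), function(sv) {
    svals <- switch(sv, pt = pt, pn = pn, pm = pm)
    fit <- cox_fit(time, event,
                   stats::setNames(data.frame(metric, svals),
                                   c(metric_name, sv)))
    row <- fit[fit$term == metric_name, , drop = FALSE]
    row$adjusted_for <- sv
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.til_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (n=%s, events=%s)\n",
              attr(x, "n"), attr(x, "n_event")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
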