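# Distributional validation of a (synthetic or real) cohort against the
# shape features reported for surgical CRC series.

sample_excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

#' Distributional validation of a cohort
#'
#' Computes the score panel and checks the distributional signatures expected
#' of intra-tumoral lymphocyte data:
#'
#' * `cd3_normality_rejected` — the skewness/kurtosis omnibus test
#'   ([normality_test()]) rejects normality of CD3+ density at alpha = 0.05
#'   (CD3 density is right-skewed and potentially bimodal);
#' * `cd8_excess_kurtosis_positive` — sample excess kurtosis of CD8+ density
#'   is positive;
#' * `cd3_density_cov_negative`, `cd8_density_cov_negative` — Spearman
#'   correlation between density and the heterogeneity coefficient is
#'   negative (heterogeneity inversely proportional to density).
#'
#' Checks that cannot be evaluated (e.g. constant densities, for which the
#' normality test is undefined) are flagged with `pass = NA` and an
#' explanatory note rather than failed.
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]); nonempty.
#' @param alpha Significance level for the normality check (default 0.05).
#' @return An object of class `til_validation`: a `data.frame` with columns
#'   `check`, `statistic`, `p`, `pass`, `note`.
#' @export
validate_cohort <- function(cohort, alpha = 0.05) {
  if (is.null(cohort) || nrow(cohort) == 0) stop("cohort must be nonempty")
  panel <- compute_panel(cohort)

  checks <- list()
  add <- function(check, statistic, p, pass, note = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, statistic = statistic, p = p, pass = pass, note = note)
  }

  cd3 <- panel$cd3_density
  if (stats::sd(cd3) == 0) {
    add("cd3_normality_rejected", NA_real_, NA_real_, NA,
        "constant CD3 density: normality test inapplicable")
  } else {
    nt <- normality_test(cd3)
    add("cd3_normality_rejected", nt$statistic, nt$p, nt$p < alpha)
  }

  ek <- sample_excess_kurtosis(panel$cd8_density)
  if (is.na(ek)) {
    add("cd8_excess_kurtosis_positive", NA_real_, NA_real_, NA,
        "constant CD8 density: kurtosis undefined")
  } else {
    add("cd8_excess_kurtosis_positive", ek, NA_real_, ek > 0)
  }

  for (marker in c("cd3", "cd8")) {
    dens <- panel[[paste0(marker, "_density")]]
    cov <- panel[[paste0(marker, "_cov")]]
    keep <- !is.na(dens) & !is.na(cov)
    if (sum(keep) < 4 || length(unique(dens[keep])) < 2 ||
        length(unique(cov[keep])) < 2) {
      add(paste0(marker, "_density_cov_negative"), NA_real_, NA_real_, NA,
          "too few informative tumors for a rank correlation")
    } else {
      sp <- spearman_assoc(dens[keep], cov[keep])
      add(paste0(marker, "_density_cov_negative"), sp$rho, sp$p, sp$rho < 0)
    }
  }

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  class(out) <- c("til_validation", "data.frame")
  out
}

#' @export
print.til_validation <- function(x, ...) {
  cat("Cohort distributional validation\n")
  for (i in seq_len(nrow(x))) {
    status <- if (is.na(x$pass[i])) "flagged" else if (x$pass[i]) "pass" else "FAIL"
    cat(sprintf("  [%s] %-30s statistic=%s p=%s %s\n", status, x$check[i],
                format(x$statistic[i], digits = 3),
                format(x$p[i], digits = 3),
                x$note[i]))
  }
  invisible(x)
}
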