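# Nonparametric association testing, normality testing and FDR control.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test of a location difference between two groups. For combined
#' sample sizes up to `exact_limit` the p value comes from exhaustive
#' enumeration of all group assignments of the observed values (valid with
#' ties); otherwise the tie- and continuity-corrected normal approximation is
#' used.
#'
#' @param x,y Numeric vectors for the two groups (each nonempty; combined
#'   n >= 3).
#' @param exact_limit Largest combined n for which exhaustive enumeration is
#'   used (default 10).
#' @param force_approx If `TRUE`, always use the normal approximation (used
#'   for approximation-accuracy checks).
#' @return A list with `statistic` (the U statistic for `x`), `p`, `method`,
#'   and group sizes `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p   # exact two-sided p = 0.1
#' @export
mann_whitney <- function(x, y, exact_limit = 10, force_approx = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n < 3) stop("combined sample size must be at least 3")
  comb <- c(x, y)
  r <- rank(comb)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (!force_approx && n <= exact_limit) {
    # enumerate every assignment of n1 of the observed values to group 1
    sets <- utils::combn(n, n1)
    rs <- colSums(matrix(r[sets], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    return(list(statistic = u, p = p, method = "exact enumeration",
                n1 = n1, n2 = n2))
  }
  ties <- table(comb)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) {
    p <- 1  # all observations identical
  } else {
    z <- (abs(u - mu) - 0.5) / sqrt(v)  # continuity-corrected
    p <- min(1, 2 * pnorm(-z))
  }
  list(statistic = u, p = p, method = "normal approximation (tie-corrected)",
       n1 = n1, n2 = n2)
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom, via [stats::kruskal.test()]. Intended for k >= 3 groups; k = 2 is
#' accepted for cross-checking against [mann_whitney()] (H equals the squared
#' tie-corrected rank-sum z in that case).
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length.
#' @return A list with `statistic` (H), `df`, and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("at least two groups are required")
  if (any(table(groups) == 0)) stop("every group must be nonempty")
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation (Pearson correlation of mid-ranks) with a p value from
#' the t approximation, via [stats::cor.test()]. A constant vector leaves the
#' correlation undefined; the result is then flagged with `rho = NA`.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped;
#'   at least 4 complete pairs are required.
#' @return A list with `rho`, `p`, `n`, and a `note` when undefined.
#' @export
spearman_assoc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("at least 4 complete pairs are required")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                note = "constant vector: correlation undefined"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, note = NULL)
}

# sign-preserving cube root (the Anscombe-Glynn transform can go negative)
cbrt <- function(v) sign(v) * abs(v)^(1 / 3)

#' Skewness/kurtosis omnibus normality test
#'
#' D'Agostino-Pearson K-squared test: the D'Agostino transformed skewness z
#' and the Anscombe-Glynn transformed kurtosis z are combined as
#' `K2 = z_skew^2 + z_kurt^2`, referred to a chi-square distribution with 2
#' degrees of freedom. Both component z statistics and their two-sided p
#' values are returned alongside the omnibus result.
#'
#' @param values Numeric vector, n >= 8, not constant.
#' @return A list with `skew_z`, `skew_p`, `kurt_z`, `kurt_p`, `statistic`
#'   (K2), `df` (2), and `p`.
#' @examples
#' normality_test(rlnorm(100))$p    # strongly non-normal
#' @export
normality_test <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8) stop("at least 8 observations are required")
  if (stats::sd(x) == 0) stop("constant data: normality test undefined")

  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n

  # D'Agostino (1970) transformed skewness
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # Anscombe-Glynn (1983) transformed kurtosis
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- (1 - 2 / (9 * a) -
               cbrt((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(skew_z = z_skew, skew_p = 2 * pnorm(-abs(z_skew)),
       kurt_z = z_kurt, kurt_p = 2 * pnorm(-abs(z_kurt)),
       statistic = k2, df = 2, p = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]: monotone
#' (cumulative-minimum enforced), capped at 1, order-preserving.
#'
#' @param p_raw Numeric vector of raw p values in \[0, 1\].
#' @return Adjusted p values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_raw) {
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

# t-based 95% CI of a group mean; NA when n < 2
group_summary <- function(v, conf_level = 0.95) {
  v <- v[!is.na(v)]
  n <- length(v)
  m <- mean(v)
  if (n < 2 || stats::sd(v) == 0) {
    return(c(n = n, mean = m, ci_low = NA_real_, ci_high = NA_real_))
  }
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(v) / sqrt(n)
  c(n = n, mean = m, ci_low = m - half, ci_high = m + half)
}

# covariate type used for test dispatch
covariate_type <- function(v, max_levels = 6) {
  obs <- v[!is.na(v)]
  u <- unique(obs)
  if (length(u) < 2) return("degenerate")
  if (is.character(v) || is.factor(v) || is.logical(v) || length(u) == 2) {
    if (length(u) == 2) return("binary") else return("multilevel")
  }
  if (length(u) <= max_levels && all(obs == floor(obs))) return("multilevel")
  "continuous"
}

#' Association screen of score metrics against covariates
#'
#' Tests each metric against each covariate with the test matched to the
#' covariate type: binary covariates by Mann-Whitney, categorical covariates
#' with 3+ levels by Kruskal-Wallis, continuous covariates by Spearman rank
#' correlation. Missing values are dropped pairwise per test. Within each
#' metric family the raw p values are Benjamini-Hochberg adjusted, and
#' significance flags are set at `p_adjusted < 0.05` (`*`) and `< 0.01`
#' (`**`). Per-level group means with t-based 95% confidence intervals are
#' reported for categorical covariates. Covariates with a single observed
#' level are skipped with a warning.
#'
#' @param panel A score panel `data.frame` from [compute_panel()].
#' @param metrics Character vector of metric columns to screen (default: CD3
#'   and CD8 density, their heterogeneity coefficients, and the I-score).
#' @param covariates Character vector of covariate columns (default: the
#'   clinicopathologic and mutational covariates present in the table).
#' @param fdr_level FDR level recorded with the result (default 0.05).
#' @return An object of class `til_assoc`: a list with `results` (one row per
#'   metric x covariate: test, statistic, `rho`, `p_raw`, `p_adjusted`,
#'   significance flag, n used), `group_summaries` (one row per metric x
#'   covariate level) and `fdr_level`.
#' @export
run_association_screen <- function(panel,
                                   metrics = c("cd3_density", "cd8_density",
                                               "cd3_cov", "cd8_cov", "iscore"),
                                   covariates = NULL,
                                   fdr_level = 0.05) {
  if (is.null(covariates)) {
    covariates <- intersect(
      c("age", "sex", "bmi", "family_history", "smoking", "alcohol",
        "right_sided", "lvi", "grade", "tumor_size_cm", "cea",
        "pt", "pn", "pm", "braf", "kras", "tp53", "mmr", "tmb"),
      names(panel))
  }
  missing_cols <- setdiff(c(metrics, covariates), names(panel))
  if (length(missing_cols) > 0)
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))

  rows <- list()
  grows <- list()
  for (metric in metrics) {
    for (cov in covariates) {
      mv <- panel[[metric]]
      cv <- panel[[cov]]
      keep <- !is.na(mv) & !is.na(cv)
      type <- covariate_type(cv[keep])
      if (type == "degenerate") {
        warning("covariate '", cov, "' has a single observed level; skipped")
        next
      }
      mvk <- mv[keep]; cvk <- cv[keep]
      if (type == "binary") {
        lev <- sort(unique(as.character(cvk)))
        res <- mann_whitney(mvk[as.character(cvk) == lev[1]],
                            mvk[as.character(cvk) == lev[2]])
        row <- data.frame(metric = metric, covariate = cov,
                          test = "mann_whitney", statistic = res$statistic,
                          rho = NA_real_, p_raw = res$p, n = sum(keep))
      } else if (type == "multilevel") {
        res <- kruskal_wallis(mvk, cvk)
        row <- data.frame(metric = metric, covariate = cov,
                          test = "kruskal_wallis", statistic = res$statistic,
                          rho = NA_real_, p_raw = res$p, n = sum(keep))
      } else {
        res <- spearman_assoc(cvk, mvk)
        row <- data.frame(metric = metric, covariate = cov,
                          test = "spearman", statistic = NA_real_,
                          rho = res$rho, p_raw = res$p, n = sum(keep))
      }
      rows[[length(rows) + 1]] <- row
      if (type %in% c("binary", "multilevel")) {
        for (lev in sort(unique(as.character(cvk)))) {
          gs <- group_summary(mvk[as.character(cvk) == lev])
          grows[[length(grows) + 1]] <- data.frame(
            metric = metric, covariate = cov, level = lev,
            n = gs[["n"]], mean = gs[["mean"]],
            ci_low = gs[["ci_low"]], ci_high = gs[["ci_high"]])
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  # BH within each metric's column of the screen
  results$p_adjusted <- NA_real_
  for (metric in unique(results$metric)) {
    idx <- which(results$metric == metric & !is.na(results$p_raw))
    results$p_adjusted[idx] <- bh_adjust(results$p_raw[idx])
  }
  results$significance <- ifelse(is.na(results$p_adjusted), "",
                          ifelse(results$p_adjusted < 0.01, "**",
                          ifelse(results$p_adjusted < fdr_level, "*", "")))
  group_summaries <- if (length(grows) > 0) do.call(rbind, grows) else
    data.frame()
  rownames(group_summaries) <- NULL
  structure(list(results = results, group_summaries = group_summaries,
                 fdr_level = fdr_level),
            class = "til_assoc")
}

#' @export
print.til_assoc <- function(x, ...) {
  cat("Association screen:", length(unique(x$results$metric)), "metrics x",
      length(unique(x$results$covariate)), "covariates, BH FDR at",
      x$fdr_level, "\n")
  sig <- x$results[x$results$significance != "", , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("Significant after adjustment:\n")
    print(sig[, c("metric", "covariate", "test", "p_raw", "p_adjusted",
                  "significance")], row.names = FALSE, digits = 3)
  } else cat("No associations significant after adjustment.\n")
  invisible(x)
}
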