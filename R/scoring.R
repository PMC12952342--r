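# Per-tumor lymphocyte scoring: pooled density, heterogeneity coefficient,
# mid-rank cohort percentiles, I-score and exploratory combination metrics.

#' Pooled cell density over three subregions
#'
#' Total count over total examined area, in cells/mm2. This equals the
#' area-weighted mean of the subregion densities, matching counting over the
#' entire available cross-sectional area.
#'
#' @param counts Nonnegative integer vector of length 3 (cells per subregion).
#' @param areas_mm2 Positive numeric vector of length 3 (mm2 per subregion).
#' @return Pooled density in cells/mm2.
#' @examples
#' compute_density(c(10, 20, 30), c(1, 2, 3))  # 10 cells/mm2
#' @export
compute_density <- function(counts, areas_mm2) {
  if (length(counts) != 3 || length(areas_mm2) != 3)
    stop("exactly three subregions are required")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  if (any(is.na(areas_mm2)) || any(areas_mm2 <= 0))
    stop("all areas must be strictly positive")
  sum(counts) / sum(areas_mm2)
}

#' Intra-tumoral heterogeneity coefficient
#'
#' Coefficient of variation (sample SD with n-1 denominator, divided by the
#' mean) of the three subregion densities `counts / areas`. Zero iff all three
#' subregion densities are equal; undefined (NA) when all counts are zero.
#' Unitless, and invariant to rescaling all counts and areas by a common
#' factor.
#'
#' @inheritParams compute_density
#' @return Nonnegative heterogeneity coefficient, or `NA` when the mean
#'   subregion density is zero.
#' @examples
#' compute_heterogeneity(c(10, 20, 30), c(1, 1, 1))  # sd 10 / mean 20 = 0.5
#' @export
compute_heterogeneity <- function(counts, areas_mm2) {
  if (length(counts) != 3 || length(areas_mm2) != 3)
    stop("exactly three subregions are required")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  if (any(is.na(areas_mm2)) || any(areas_mm2 <= 0))
    stop("all areas must be strictly positive")
  d <- counts / areas_mm2
  m <- mean(d)
  if (m == 0) return(NA_real_)
  stats::sd(d) / m
}

#' Mid-rank cohort percentiles
#'
#' Converts a cohort vector to percentiles by the mid-rank convention
#' `(rank - 0.5) / n * 100`, with tied values receiving the mean of their
#' ranks. Every percentile lies strictly inside (0, 100), so downstream
#' percentile ratios are always defined, and the cohort mean is exactly 50.
#' Invariant under strictly increasing transforms of the values.
#'
#' @param values Numeric cohort vector, length >= 2, no missing values.
#' @return Percentiles in (0, 100), same length and order as `values`.
#' @examples
#' percentile_rank(c(1, 2, 3, 4))    # 12.5 37.5 62.5 87.5
#' percentile_rank(c(1, 2, 2, 3))    # 12.5 50 50 87.5
#' @export
percentile_rank <- function(values) {
  if (any(is.na(values))) stop("values must not contain missing entries")
  n <- length(values)
  if (n < 2) stop("at least two values are required")
  (rank(values, ties.method = "average") - 0.5) / n * 100
}

#' Compute the per-tumor score panel for a cohort
#'
#' Appends to the cohort table the derived lymphocyte metrics:
#' * `cd3_density`, `cd8_density` — pooled densities (cells/mm2);
#' * `cd3_cov`, `cd8_cov` — heterogeneity coefficients ([compute_heterogeneity()];
#'   NA when a marker's counts are all zero);
#' * `cd3_pct`, `cd8_pct` — mid-rank cohort percentiles of the densities;
#' * `iscore` — (cd3_pct + cd8_pct) / 2, the percentile-averaged I-score;
#' * `diff_density = cd3_density - cd8_density`, `diff_pct = cd3_pct - cd8_pct`;
#' * `ratio_density = cd3_density / cd8_density` (NA when `cd8_density` is 0),
#'   `ratio_pct = cd3_pct / cd8_pct` (always defined: mid-rank percentiles are
#'   strictly positive).
#'
#' @param cohort A cohort `data.frame` with the subregion count and area
#'   columns (see [generate_cohort()]); at least 2 rows.
#' @return The cohort with the panel columns appended.
#' @examples
#' panel <- compute_panel(generate_cohort(simulation_config(n_patients = 30)))
#' mean(panel$iscore)  # exactly 50 when densities are tie-free
#' @export
compute_panel <- function(cohort) {
  need <- c(paste0("cd3_count_", 1:3), paste0("cd8_count_", 1:3),
            paste0("area_mm2_", 1:3))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) < 2) stop("at least two tumors are required for percentiles")

  c3 <- as.matrix(cohort[paste0("cd3_count_", 1:3)])
  c8 <- as.matrix(cohort[paste0("cd8_count_", 1:3)])
  ar <- as.matrix(cohort[paste0("area_mm2_", 1:3)])
  if (any(ar <= 0)) stop("all areas must be strictly positive")
  if (any(c3 < 0) || any(c8 < 0)) stop("counts must be nonnegative")

  cohort$cd3_density <- rowSums(c3) / rowSums(ar)
  cohort$cd8_density <- rowSums(c8) / rowSums(ar)
  row_cv <- function(counts, areas) {
    d <- counts / areas
    m <- rowMeans(d)
    s <- sqrt(pmax(rowSums((d - m)^2), 0) / (ncol(d) - 1))
    ifelse(m == 0, NA_real_, s / m)
  }
  cohort$cd3_cov <- row_cv(c3, ar)
  cohort$cd8_cov <- row_cv(c8, ar)
  cohort$cd3_pct <- percentile_rank(cohort$cd3_density)
  cohort$cd8_pct <- percentile_rank(cohort$cd8_density)
  cohort$iscore <- (cohort$cd3_pct + cohort$cd8_pct) / 2
  cohort$diff_density <- cohort$cd3_density - cohort$cd8_density
  cohort$diff_pct <- cohort$cd3_pct - cohort$cd8_pct
  cohort$ratio_density <- ifelse(cohort$cd8_density == 0, NA_real_,
                                 cohort$cd3_density / cohort$cd8_density)
  cohort$ratio_pct <- cohort$cd3_pct / cohort$cd8_pct
  cohort
}

# names of the derived metric columns, in display order
panel_metrics <- function() {
  c("cd3_density", "cd3_pct", "cd3_cov",
    "cd8_density", "cd8_pct", "cd8_cov",
    "iscore", "diff_density", "diff_pct", "ratio_density", "ratio_pct")
}
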