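#' Simulation configuration for a synthetic CRC lymphocyte cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' are calibrated to the published summary characteristics of a 201-patient
#' surgical colorectal-cancer cohort: covariate prevalences (e.g. 53.2% male,
#' 11.4% active smokers, pTNM stage I-IV at 15.9/32.8/37.3/13.9%), a total
#' examined area with mean 37.3 and median 27.4 mm2, and censored
#' disease-specific survival totalling about 605 person-years. Density
#' distributions follow the reported shapes: CD3+ density is a two-component
#' lognormal mixture (right-skewed, potentially bimodal), CD8+ density a
#' single lognormal (right-skewed, kurtotic), and subregion heterogeneity
#' decreases with density via a power law.
#'
#' @param n_patients Number of tumors to simulate.
#' @param seed Integer seed; identical `(config, seed)` gives a bit-identical
#'   cohort.
#' @param cd3_mixture Two-component lognormal mixture for the latent CD3+
#'   density (cells/mm2): `weight_low`, `mu_low`, `sigma_low`, `mu_high`,
#'   `sigma_high` (log-scale parameters).
#' @param cd8_lognormal Lognormal parameters `mu`, `sigma` for the latent CD8+
#'   density (cells/mm2).
#' @param cd3_cd8_rank_correlation Target Spearman correlation between latent
#'   CD3 and CD8 densities, induced through a Gaussian copula. CD8+ cells are
#'   a subset of CD3+ cells, so this is strongly positive.
#' @param heterogeneity `dispersion_at_reference` (coefficient of variation of
#'   subregion densities at `reference_density` cells/mm2) and
#'   `density_exponent` (<= 0): CV(d) = CV_ref * (d / d_ref)^exponent, so
#'   lower-density tumors are more heterogeneous.
#' @param subregion_area `mean_total_mm2` and `variation` (log-scale SD) of
#'   the lognormal total examined area, split over three subregions.
#' @param covariate_prevalences Named list of binary prevalences and
#'   multinomial level probabilities (grade, pT, pN) for the clinicopathologic
#'   and mutation covariates. `lvi_missing` is the fraction of tumors with
#'   unevaluable lymphovascular invasion.
#' @param covariate_scales Location/scale parameters for the continuous
#'   covariates (age, BMI, tumor size, CEA, TMB).
#' @param density_effects Log-scale shifts of the latent densities by
#'   covariates, inducing the sex / smoking / stage / mutation associations
#'   seen in the score panel.
#' @param effect_sizes Named numeric vector of log-hazard coefficients used to
#'   draw survival: `cd8_per100` (per 100 cells/mm2 of measured CD8+ density),
#'   `pt`, `pn` (per ordinal level) and `pm` (binary).
#' @param baseline_hazard Events per person-year at the reference covariate
#'   pattern (pT3, pN1, pM0, CD8 90 cells/mm2).
#' @param censoring `admin_horizon_years` (administrative censoring) and
#'   `random_censor_rate` (exponential loss to follow-up, per person-year).
#'
#' @return An object of class `til_sim_config` (a validated list).
#' @seealso [generate_cohort()], [validate_cohort()]
#' @examples
#' cfg <- simulation_config(n_patients = 50, seed = 42)
#' cohort <- generate_cohort(cfg)
#' @export
simulation_config <- function(n_patients = 201,
                              seed = 1L,
                              cd3_mixture = list(weight_low = 0.55,
                                                 mu_low = log(70), sigma_low = 0.40,
                                                 mu_high = log(260), sigma_high = 0.35),
                              cd8_lognormal = list(mu = log(65), sigma = 0.85),
                              cd3_cd8_rank_correlation = 0.6,
                              heterogeneity = list(dispersion_at_reference = 0.45,
                                                   density_exponent = -0.4,
                                                   reference_density = 100),
                              subregion_area = list(mean_total_mm2 = 37.3,
                                                    variation = 0.785),
                              covariate_prevalences = list(
                                male = 0.532, smoking = 0.114, alcohol = 0.215,
                                family_history = 0.13, right_sided = 0.53,
                                lvi = 0.361, lvi_missing = 0.174,
                                grade = c(0.050, 0.775, 0.175),
                                pt = c(0.040, 0.155, 0.585, 0.220),
                                pn = c(0.495, 0.345, 0.160),
                                pm = 0.149,
                                braf = 0.249, kras = 0.100, tp53 = 0.239,
                                mmr = 0.259),
                              covariate_scales = list(
                                age_mean = 67.5, age_sd = 13.4,
                                age_min = 21, age_max = 95,
                                bmi_mean = 29.5, bmi_sd = 6.8,
                                bmi_min = 15, bmi_max = 60,
                                size_meanlog = 1.48, size_sdlog = 0.46,
                                cea_meanlog = 1.10, cea_sdlog = 1.50,
                                tmb_meanlog = 1.40, tmb_sdlog = 0.60,
                                tmb_mmr_shift = 2.10),
                              density_effects = list(
                                cd3 = c(female = 0.20, smoking = -0.35,
                                        stage = -0.25, mmr = 0.40),
                                cd8 = c(female = 0.15, smoking = -0.35,
                                        stage = -0.30, mmr = 0.50,
                                        braf = 0.50, age = 0.15)),
                              effect_sizes = c(cd8_per100 = -0.8, pt = 0.4,
                                               pn = 0.5, pm = 0.9),
                              baseline_hazard = 0.05,
                              censoring = list(admin_horizon_years = 10,
                                               random_censor_rate = 0.25)) {
  cfg <- list(n_patients = n_patients,
              seed = seed,
              cd3_mixture = cd3_mixture,
              cd8_lognormal = cd8_lognormal,
              cd3_cd8_rank_correlation = cd3_cd8_rank_correlation,
              heterogeneity = heterogeneity,
              subregion_area = subregion_area,
              covariate_prevalences = covariate_prevalences,
              covariate_scales = covariate_scales,
              density_effects = density_effects,
              effect_sizes = effect_sizes,
              baseline_hazard = baseline_hazard,
              censoring = censoring)
  class(cfg) <- "til_sim_config"
  validate_config(cfg)
  cfg
}

# stop() with the offending field name, per the generator's error contract
config_check <- function(ok, field, why) {
  if (!isTRUE(ok)) stop("invalid simulation config: field '", field, "' ", why,
                        call. = FALSE)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Validate a simulation configuration
#'
#' Checks the invariants of a [simulation_config()] object: probabilities and
#' mixture weights in \[0, 1\] (weights summing to 1), strictly positive scale
#' and area parameters, non-positive heterogeneity exponent, and a
#' well-formed effect-size vector. Called internally by [simulation_config()]
#' and [generate_cohort()].
#'
#' @param config A `til_sim_config` object.
#' @return `config`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_config <- function(config) {
  config_check(is.numeric(config$n_patients) && length(config$n_patients) == 1 &&
                 config$n_patients >= 1 && config$n_patients == floor(config$n_patients),
               "n_patients", "must be a positive integer")
  config_check(is.numeric(config$seed) && length(config$seed) == 1 &&
                 is.finite(config$seed),
               "seed", "must be a single finite number")

  m <- config$cd3_mixture
  config_check(all(c("weight_low", "mu_low", "sigma_low", "mu_high", "sigma_high")
                   %in% names(m)), "cd3_mixture", "is missing components")
  config_check(is_prob(m$weight_low), "cd3_mixture$weight_low", "must lie in [0, 1]")
  config_check(m$sigma_low > 0 && m$sigma_high > 0,
               "cd3_mixture", "sigmas must be strictly positive")
  config_check(config$cd8_lognormal$sigma > 0,
               "cd8_lognormal$sigma", "must be strictly positive")
  config_check(is_prob(config$cd3_cd8_rank_correlation),
               "cd3_cd8_rank_correlation", "must lie in [0, 1]")

  h <- config$heterogeneity
  config_check(h$dispersion_at_reference > 0,
               "heterogeneity$dispersion_at_reference", "must be positive")
  config_check(h$density_exponent <= 0,
               "heterogeneity$density_exponent", "must be <= 0")
  config_check(h$reference_density > 0,
               "heterogeneity$reference_density", "must be positive")

  config_check(config$subregion_area$mean_total_mm2 > 0,
               "subregion_area$mean_total_mm2", "must be positive")
  config_check(config$subregion_area$variation >= 0,
               "subregion_area$variation", "must be nonnegative")

  pv <- config$covariate_prevalences
  for (nm in c("male", "smoking", "alcohol", "family_history", "right_sided",
               "lvi", "lvi_missing", "pm", "braf", "kras", "tp53", "mmr")) {
    config_check(is_prob(pv[[nm]]) && length(pv[[nm]]) == 1,
                 paste0("covariate_prevalences$", nm), "must be one value in [0, 1]")
  }
  for (nm in c("grade", "pt", "pn")) {
    config_check(is_prob(pv[[nm]]) && abs(sum(pv[[nm]]) - 1) < 1e-8,
                 paste0("covariate_prevalences$", nm),
                 "must be level probabilities summing to 1")
  }

  es <- config$effect_sizes
  config_check(is.numeric(es) && all(c("cd8_per100", "pt", "pn", "pm") %in% names(es)),
               "effect_sizes",
               "must be a named numeric vector with cd8_per100, pt, pn, pm")
  config_check(config$baseline_hazard > 0, "baseline_hazard", "must be positive")
  config_check(config$censoring$admin_horizon_years > 0,
               "censoring$admin_horizon_years", "must be positive")
  config_check(config$censoring$random_censor_rate >= 0,
               "censoring$random_censor_rate", "must be nonnegative")
  invisible(config)
}

#' @export
print.til_sim_config <- function(x, ...) {
  cat("Synthetic CRC TIL cohort configuration\n")
  cat("  patients:", x$n_patients, "  seed:", x$seed, "\n")
  cat(sprintf("  CD3 latent density: lognormal mixture (w_low=%.2f, modes ~%.0f/%.0f cells/mm2)\n",
              x$cd3_mixture$weight_low, exp(x$cd3_mixture$mu_low),
              exp(x$cd3_mixture$mu_high)))
  cat(sprintf("  CD8 latent density: lognormal (median %.0f cells/mm2, sigma %.2f)\n",
              exp(x$cd8_lognormal$mu), x$cd8_lognormal$sigma))
  cat(sprintf("  heterogeneity: CV %.2f at %g cells/mm2, exponent %.2f\n",
              x$heterogeneity$dispersion_at_reference,
              x$heterogeneity$reference_density, x$heterogeneity$density_exponent))
  cat(sprintf("  survival: baseline %.3f events/py; log-HRs %s\n",
              x$baseline_hazard,
              paste(names(x$effect_sizes), sprintf("%.2f", x$effect_sizes),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
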