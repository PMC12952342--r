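# Kaplan-Meier, log-rank, Cox proportional hazards and stage adjustment.

test_that("Kaplan-Meier reproduces closed forms and the hand-computed example", {
  # no events: survival identically 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # three subjects, events at 1, 2, 3
  km3 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km3$surv[km3$time > 0], c(2 / 3, 1 / 3, 0))
  # six subjects with censoring: product-limit by hand
  # events at 1, 3, 5, 6; censored at 2+, 4+
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 0, 1, 1)
  km6 <- km_estimate(time, event)
  steps <- km6[km6$n_event > 0, ]
  expect_equal(steps$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2, 0))
  expect_equal(steps$surv, naive_km(time, event)$surv)
  expect_error(km_estimate(c(1, 2), c(1, 0), c("a", NA)), "missing")
})

test_that("KM curves start at 1 and are nonincreasing; match ECDF sans censoring", {
  co <- generate_cohort(simulation_config(n_patients = 120, seed = 23))
  km <- km_estimate(co$followup_years, co$dss_event,
                    ifelse(co$stage >= 3, "late", "early"))
  for (g in unique(km$group)) {
    s <- km$surv[km$group == g]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }
  withr::with_seed(24, {
    t_all <- rexp(50, 0.3)
    km_all <- km_estimate(t_all, rep(1, 50))
    emp <- vapply(km_all$time, function(tt) mean(t_all > tt), numeric(1))
    expect_equal(km_all$surv, emp)
  })
})

test_that("log-rank: null, symmetry, flagged zero events, O-E/V oracle", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 0, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 4)  # identical copies
  lr <- log_rank(time, event, grp)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)

  withr::with_seed(25, {
    t2 <- round(rexp(30, 0.3), 1) + 0.1
    e2 <- rbinom(30, 1, 0.7)
    g2 <- rbinom(30, 1, 0.5)
    a <- log_rank(t2, e2, g2)
    b <- log_rank(t2, e2, 1 - g2)  # swapped labels
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p, b$p)
    expect_equal(a$statistic, naive_logrank(t2, e2, g2)$chisq)
  })

  # eight-subject worked example against the hand O-E/V table
  t8 <- c(1, 2, 3, 4, 2, 3, 5, 6)
  e8 <- c(1, 1, 0, 1, 1, 1, 1, 0)
  g8 <- rep(c("x", "y"), each = 4)
  expect_equal(log_rank(t8, e8, g8)$statistic,
               naive_logrank(t8, e8, g8)$chisq)

  flagged <- log_rank(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 1, 2, 2))
  expect_true(is.na(flagged$statistic))
  expect_match(flagged$note, "no events")
})

test_that("Cox fit: explicit error states", {
  d <- make_surv_data(40, beta = 0.5, seed = 26)
  expect_error(cox_fit(d$time, rep(0, 40), d$x), "no events")
  expect_error(cox_fit(d$time, d$event, rep(3, 40)), "constant covariate")
  expect_error(cox_fit(d$time, d$event, cbind(a = d$x, b = 2 * d$x)),
               "collinear")
})

test_that("Cox recovers a rate ratio of 2 on two-group exponential data", {
  withr::with_seed(27, {
    g <- rep(0:1, each = 1000)
    time <- rexp(2000, 0.2 * 2^g)
    fit <- cox_fit(time, rep(1, 2000), g)
    expect_lt(abs(fit$coef[1] - log(2)), 3 * fit$se[1])
    expect_true(fit$ci_low[1] <= fit$hr[1] & fit$hr[1] <= fit$ci_high[1])
    expect_equal(fit$hr[1], exp(fit$coef[1]))
  })
})

test_that("Cox coefficient maximizes the Efron partial likelihood", {
  for (s in 1:3) {
    d <- make_surv_data(50, beta = 0.6, seed = 30 + s, round_times = TRUE)
    fit <- cox_fit(d$time, d$event, d$x)
    b_grid <- grid_max_efron(d$time, d$event, d$x)
    expect_lt(abs(fit$coef[1] - b_grid), 1e-4)
    # oracle dominance: the returned coefficient beats every coarse grid point
    grid <- seq(-3, 3, by = 0.05)
    ll_fit <- efron_loglik(fit$coef[1], d$time, d$event, d$x)
    ll_grid <- vapply(grid, efron_loglik, numeric(1),
                      time = d$time, event = d$event, x = d$x)
    expect_true(all(ll_fit >= ll_grid - 1e-10))
    expect_equal(attr(fit, "loglik"), ll_fit, tolerance = 1e-8)
  }
})

test_that("Cox score test at beta=0 equals the log-rank statistic (tie-free)", {
  for (s in 1:5) {
    d <- make_surv_data(60, beta = 0.4, seed = 40 + s)
    g <- as.integer(d$x > 0)
    if (sum(d$event) == 0 || length(unique(g)) < 2) next
    fit <- cox_fit(d$time, d$event, g, ties = "breslow")
    lr <- log_rank(d$time, d$event, g)
    expect_equal(attr(fit, "score_test"), lr$statistic, tolerance = 1e-6)
  }
})

test_that("stage-adjusted fit returns the metric row; collinearity is flagged", {
  co <- compute_panel(generate_cohort(simulation_config(seed = 28)))
  joint <- stage_adjusted_fit(co$followup_years, co$dss_event,
                              co$cd8_density, co$pt, co$pn, co$pm,
                              metric_name = "cd8_density")
  expect_equal(nrow(joint), 1)
  expect_equal(joint$term, "cd8_density")
  model <- attr(joint, "model")
  expect_setequal(model$term, c("cd8_density", "pt", "pn", "pm"))

  indiv <- stage_adjusted_fit(co$followup_years, co$dss_event,
                              co$cd8_density, co$pt, co$pn, co$pm,
                              mode = "individual", metric_name = "cd8_density")
  expect_equal(indiv$adjusted_for, c("pt", "pn", "pm"))
  expect_equal(nrow(indiv), 3)

  # a metric that is a deterministic function of pT cannot be separated
  expect_error(stage_adjusted_fit(co$followup_years, co$dss_event,
                                  2 * co$pt + 1, co$pt, co$pn, co$pm),
               "collinear")
})

test_that("a stage-driven effect attenuates once stage enters the model", {
  # survival depends only on stage; the metric is prognostic only through its
  # stage correlation, so adjustment should pull its coefficient toward zero
  cfg <- simulation_config(
    n_patients = 2000, seed = 29,
    effect_sizes = c(cd8_per100 = 0, pt = 0.4, pn = 0.5, pm = 0.9),
    density_effects = list(
      cd3 = c(female = 0.2, smoking = -0.35, stage = -0.25, mmr = 0.4),
      cd8 = c(female = 0.15, smoking = -0.35, stage = -0.6, mmr = 0.5,
              braf = 0.5, age = 0.15)))
  co <- compute_panel(generate_cohort(cfg))
  uni <- cox_fit(co$followup_years, co$dss_event,
                 data.frame(cd8_per100 = co$cd8_density / 100))
  adj <- stage_adjusted_fit(co$followup_years, co$dss_event,
                            co$cd8_density / 100, co$pt, co$pn, co$pm,
                            metric_name = "cd8_per100")
  expect_lt(uni$coef[1], 0)                    # univariable looks protective
  expect_lt(uni$p[1], 0.05)
  expect_lt(abs(adj$coef[1]), abs(uni$coef[1]))  # attenuation toward 0
  expect_true(adj$ci_low[1] <= 1 & 1 <= adj$ci_high[1])  # true adjusted HR 1
})

test_that("stage-adjusted null metric rejects near the nominal rate", {
  rejections <- vapply(1:100, function(s) {
    co <- generate_cohort(simulation_config(n_patients = 201, seed = 4000 + s))
    noise <- withr::with_seed(9000 + s, rnorm(201))
    adj <- stage_adjusted_fit(co$followup_years, co$dss_event, noise,
                              co$pt, co$pn, co$pm)
    adj$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.10)
})
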