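# Nonparametric tests, the normality omnibus, BH adjustment, and the
# association screen.

test_that("Mann-Whitney exact enumeration reproduces closed-form cases", {
  same <- mann_whitney(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$statistic, 3 * 3 / 2)
  expect_equal(same$p, 1)
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p, 0.1)  # most extreme of C(6,3)=20 orderings, two-sided
  expect_match(sep$method, "exact")
  expect_error(mann_whitney(numeric(0), c(1, 2)), "nonempty")
})

test_that("Mann-Whitney approximation tracks the exact permutation p", {
  withr::with_seed(12, {
    for (i in 1:20) {
      x <- sample(1:15, 10, replace = TRUE)
      y <- sample(4:18, 10, replace = TRUE)
      p_exact <- naive_mw_exact_p(x, y)
      p_approx <- mann_whitney(x, y, force_approx = TRUE)$p
      expect_lt(abs(p_exact - p_approx), 0.02)
    }
  })
})

test_that("rank tests are invariant under strictly increasing transforms", {
  withr::with_seed(13, {
    x <- rlnorm(14, 3, 1); y <- rlnorm(11, 3.4, 1)
    f <- function(v) log(v)^3 + v / 100
    expect_equal(mann_whitney(x, y)$p, mann_whitney(f(x), f(y))$p)
    vals <- c(x, y, rlnorm(9, 3.2, 1))
    g <- rep(1:3, c(14, 11, 9))
    expect_equal(kruskal_wallis(vals, g)$statistic,
                 kruskal_wallis(f(vals), g)$statistic)
    z <- rnorm(12)
    w <- z + rnorm(12)
    expect_equal(spearman_assoc(f(exp(z)), w)$rho,
                 spearman_assoc(exp(z), w)$rho)
  })
})

test_that("Kruskal-Wallis: null case, k=2 identity, permutation oracle", {
  vals <- rep(c(3, 7, 7, 9), 3)
  g <- rep(1:3, each = 4)
  kw0 <- kruskal_wallis(vals, g)  # three identical groups
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  expect_error(kruskal_wallis(c(1, 2), c(1, 1)), "two groups")

  # k = 2: H equals the squared tie-corrected rank-sum z
  withr::with_seed(14, {
    x <- sample(1:9, 8, TRUE); y <- sample(3:12, 7, TRUE)
    n1 <- 8; n2 <- 7; n <- 15
    r <- rank(c(x, y))
    u <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
    ties <- table(c(x, y))
    v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z2 <- (u - n1 * n2 / 2)^2 / v
    expect_equal(kruskal_wallis(c(x, y), rep(1:2, c(n1, n2)))$statistic, z2)
  })

  # small instance: chi-square p within 0.03 of the exhaustive permutation p
  vals <- c(0, -0.2, -1.4, 0.2, 1.1, 1.2, 0.4, 1.2, 0)
  g <- rep(1:3, each = 3)
  h_obs <- kruskal_wallis(vals, g)$statistic
  cnt <- 0; tot <- 0
  first <- utils::combn(9, 3)
  for (i in seq_len(ncol(first))) {
    rest <- setdiff(1:9, first[, i])
    second <- utils::combn(6, 3)
    for (j in seq_len(ncol(second))) {
      lab <- integer(9)
      lab[first[, i]] <- 1
      lab[rest[second[, j]]] <- 2
      lab[lab == 0] <- 3
      tot <- tot + 1
      if (kruskal_wallis(vals, lab)$statistic >= h_obs - 1e-9) cnt <- cnt + 1
    }
  }
  expect_lt(abs(kruskal_wallis(vals, g)$p - cnt / tot), 0.03)
})

test_that("Spearman: monotone extremes, constant flag, permutation oracle", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearman_assoc(x, x^3 + 2)$rho, 1)
  expect_equal(spearman_assoc(x, -log(x))$rho, -1)
  cns <- spearman_assoc(rep(1, 6), rnorm(6))
  expect_true(is.na(cns$rho))
  expect_match(cns$note, "constant")
  expect_error(spearman_assoc(1:3, 3:1), "4 complete pairs")

  xx <- c(1.3, 2.1, 3.7, 4.2, 5.9, 6.1)
  yy <- c(2.0, 1.1, 4.5, 3.9, 5.2, 7.3)
  sp <- spearman_assoc(xx, yy)
  rho_obs <- abs(sp$rho)
  hits <- sum(vapply(perms_of(seq_along(yy)), function(p)
    abs(cor(xx, yy[p], method = "spearman")) >= rho_obs - 1e-9, logical(1)))
  expect_lt(abs(sp$p - hits / factorial(6)), 0.05)
})

test_that("normality omnibus: type-I error near nominal on Gaussian data", {
  rejections <- withr::with_seed(15, {
    vapply(1:2000, function(i) normality_test(rnorm(201))$p < 0.05,
           logical(1))
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("normality omnibus: high power on the bimodal CD3 mixture", {
  power <- withr::with_seed(16, {
    mx <- simulation_config()$cd3_mixture
    mean(vapply(1:200, function(i) {
      comp <- rbinom(201, 1, 1 - mx$weight_low)
      x <- rlnorm(201, ifelse(comp == 1, mx$mu_high, mx$mu_low),
                  ifelse(comp == 1, mx$sigma_high, mx$sigma_low))
      normality_test(x)$p < 0.05
    }, logical(1)))
  })
  expect_gte(power, 0.9)
})

test_that("skewness z is centred at zero for symmetric data", {
  zbar <- withr::with_seed(17, {
    mean(vapply(1:100, function(i) normality_test(runif(2000))$skew_z,
                numeric(1)))
  })
  expect_lt(abs(zbar), 0.3)
  expect_error(normality_test(rep(2, 50)), "constant")
  expect_error(normality_test(rnorm(5)), "at least 8")
})

test_that("BH step-up: hand-computed cases and invariances", {
  expect_equal(bh_adjust(0.32), 0.32)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(18, {
    p <- runif(12)^2
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # concordant ordering and permutation equivariance
    expect_equal(order(adj[order(p)]), seq_along(p))
    perm <- sample(12)
    expect_equal(bh_adjust(p[perm]), adj[perm])
    # direct step-up oracle
    o <- order(p)
    stepped <- rev(cummin(rev(pmin(1, p[o] * 12 / seq_len(12)))))
    expect_equal(adj[o], stepped)
  })
})

test_that("association screen dispatches the test matched to covariate type", {
  panel <- compute_panel(generate_cohort(simulation_config(seed = 19)))
  scr <- run_association_screen(panel, metrics = c("cd3_density", "iscore"))
  res <- scr$results
  expect_equal(unique(res$test[res$covariate == "sex"]), "mann_whitney")
  expect_equal(unique(res$test[res$covariate == "grade"]), "kruskal_wallis")
  expect_equal(unique(res$test[res$covariate == "pt"]), "kruskal_wallis")
  expect_equal(unique(res$test[res$covariate == "age"]), "spearman")
  expect_equal(unique(res$test[res$covariate == "mmr"]), "mann_whitney")
  # rho only for spearman rows
  expect_true(all(is.na(res$rho[res$test != "spearman"])))
  expect_true(all(!is.na(res$rho[res$test == "spearman"])))
  # adjusted p never below raw p, both in [0, 1]
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12))
  expect_true(all(res$p_raw >= 0 & res$p_adjusted <= 1))
  # LVI has missing values: its tests use fewer tumors
  expect_lt(res$n[res$covariate == "lvi"][1], nrow(panel))
  # group summaries carry t-based CIs bracketing the mean
  gs <- scr$group_summaries
  expect_true(all(gs$ci_low <= gs$mean & gs$mean <= gs$ci_high, na.rm = TRUE))
})

test_that("degenerate and confounded covariates are handled", {
  panel <- compute_panel(generate_cohort(simulation_config(n_patients = 80,
                                                           seed = 20)))
  panel$one_level <- 1
  expect_warning(
    run_association_screen(panel, metrics = "cd3_density",
                           covariates = c("sex", "one_level")),
    "single observed level")
  # metric identical to the covariate: no rearrangement of the metric values
  # across the two groups can achieve a smaller p
  panel$confound <- as.integer(panel$cd3_density > median(panel$cd3_density))
  scr <- run_association_screen(panel, metrics = "confound",
                                covariates = "confound")
  p_conf <- scr$results$p_raw[1]
  shuffled <- withr::with_seed(22, {
    vapply(1:50, function(i) {
      m <- sample(panel$confound)
      mann_whitney(m[panel$confound == 0], m[panel$confound == 1])$p
    }, numeric(1))
  })
  expect_true(all(p_conf <= shuffled + 1e-12))
  expect_lt(p_conf, 1e-12)
})
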