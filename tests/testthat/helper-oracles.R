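# Independent, naively coded oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# mid-rank percentile by direct counting
naive_percentile <- function(values) {
  n <- length(values)
  sapply(values, function(v) {
    r <- sum(values < v) + (sum(values == v) + 1) / 2
    (r - 0.5) / n * 100
  })
}

# coefficient of variation by a two-pass SD
naive_cv <- function(d) {
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  s / m
}

# exact two-sided Mann-Whitney p by enumerating group assignments
naive_mw_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  comb <- c(x, y)
  r <- rank(comb)
  mu <- n1 * length(y) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, function(s) sum(r[s])) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# hand-rolled product-limit estimator
naive_km <- function(time, event) {
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in sort(unique(time[event == 1]))) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# hand-rolled two-group log-rank from the O-E/V table
naive_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# exhaustive cutpoint enumeration: loop every distinct value, survdiff each
naive_scan <- function(x, time, event, min_group_fraction = 0.10) {
  n <- length(x)
  rows <- NULL
  for (v in sort(unique(x))) {
    n_low <- sum(x <= v)
    n_high <- n - n_low
    if (n_low < min_group_fraction * n || n_high < min_group_fraction * n)
      next
    grp <- x > v
    sdf <- survival::survdiff(survival::Surv(time, event) ~ grp)
    rows <- rbind(rows, data.frame(
      cutoff = v, n_low = n_low, n_high = n_high, chisq = sdf$chisq,
      p = pchisq(sdf$chisq, 1, lower.tail = FALSE)))
  }
  rows
}

# optimum from the naive scan under the same tie-break (smallest threshold)
naive_scan_best <- function(scan) {
  best <- which(scan$p == min(scan$p))
  best <- best[which.min(scan$cutoff[best])]
  scan[best, ]
}

# Efron partial log-likelihood for a single covariate, written directly from
# the definition
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    tied <- event == 1 & time == t
    d <- sum(tied)
    s_risk <- sum(exp(beta * x[risk]))
    s_tied <- sum(exp(beta * x[tied]))
    ll <- ll + beta * sum(x[tied]) -
      sum(log(s_risk - (seq_len(d) - 1) / d * s_tied))
  }
  ll
}

# two-stage grid maximization of the Efron partial likelihood
grid_max_efron <- function(time, event, x, span = 3) {
  g1 <- seq(-span, span, by = 0.01)
  ll1 <- sapply(g1, efron_loglik, time = time, event = event, x = x)
  b1 <- g1[which.max(ll1)]
  g2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-5)
  ll2 <- sapply(g2, efron_loglik, time = time, event = event, x = x)
  g2[which.max(ll2)]
}

# all permutations of a small vector, by recursion
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# random survival data with a single covariate effect
make_surv_data <- function(n, beta = 0.5, seed = 1, cens_rate = 0.15,
                           round_times = FALSE) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    t_event <- rexp(n, 0.2 * exp(beta * x))
    t_cens <- rexp(n, cens_rate)
    time <- pmin(t_event, t_cens)
    if (round_times) time <- pmax(round(time, 1), 0.1)
    event <- as.integer(t_event <= t_cens)
    list(x = x, time = time, event = event)
  })
}
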