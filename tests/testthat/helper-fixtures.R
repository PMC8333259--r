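# Shared fixtures: small cohorts and hand-built survival toys.

small_cohort <- function(n = 80, seed = 42, ...) {
  generate_cohort(synthetic_config(n_subjects = n, seed = seed, ...))
}

# Reference covariate table: every factor at its first (reference) level.
reference_covariates <- function(n, config) {
  out <- data.frame(subject_id = seq_len(n))
  for (nm in names(config$covariate_prevalences)) {
    lv <- names(config$covariate_prevalences[[nm]])
    out[[nm]] <- factor(rep(lv[1], n), levels = lv)
  }
  out$fbs <- rep(100, n)
  out
}

# Balanced one-way layout: k subjects, m replicate measurements each.
balanced_oneway <- function(k, m, mu = 10, sigma_u = 1, sigma_e = 0.5,
                            seed = 1) {
  set.seed(seed)
  u <- rnorm(k, 0, sigma_u)
  data.frame(
    subject_id = rep(seq_len(k), each = m),
    time = rep(seq_len(m), k),
    y = mu + rep(u, each = m) + rnorm(k * m, 0, sigma_e)
  )
}

# Four-record survival toy: death at 1, censored at 2, deaths at 3 and 4.
km_toy <- function() {
  data.frame(subject_id = 1:4, time = c(1, 2, 3, 4), event = c(1, 0, 1, 1))
}

# Two-group toy for the log-rank brute-force oracle.
logrank_toy <- function() {
  data.frame(subject_id = 1:4, time = c(1, 3, 2, 4), event = c(1, 0, 1, 1),
             grp = factor(c("a", "a", "b", "b")))
}

# Independent product-limit computation (no survival-package calls).
km_by_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_, at_risk = NA_integer_,
                    events = NA_integer_)
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s; out$at_risk[i] <- n_risk; out$events[i] <- d
  }
  out
}

# Brute-force log-rank: observed minus expected with hypergeometric
# variance, accumulated over distinct event times.
logrank_by_hand <- function(time, event, grp) {
  grp <- factor(grp)
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  g1 <- levels(grp)[1]
  for (tt in ut) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# Breslow log partial likelihood for a single numeric covariate.
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
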