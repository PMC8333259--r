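test_that("a single observation per subject is refused as non-identifiable", {
  df <- data.frame(subject_id = 1:30, time = 0, sqrt_sbp = rnorm(30, 11, 1))
  expect_error(fit_lmm(df, lmm_spec(fixed_terms = character(0))),
               "not identifiable")
})

test_that("balanced one-way REML components equal the ANOVA estimators", {
  k <- 10; m <- 5
  df <- balanced_oneway(k, m, seed = 3)
  fit <- fit_lmm(df, lmm_spec(response = "y", fixed_terms = character(0),
                              random_terms = "intercept",
                              cov_structure = "IND", method = "REML"))
  # closed-form oracle: MSE and (MSB - MSE) / m from the one-way ANOVA table
  ybar_i <- tapply(df$y, df$subject_id, mean)
  ybar <- mean(df$y)
  msb <- m * sum((ybar_i - ybar)^2) / (k - 1)
  mse <- sum((df$y - ybar_i[as.character(df$subject_id)])^2) / (k * (m - 1))
  expect_equal(unname(fit$sigma_params["sigma_e"]^2), mse, tolerance = 1e-5)
  expect_equal(unname(fit$varcomp["sigma_u0"]^2), (msb - mse) / m,
               tolerance = 1e-5)
  expect_equal(unname(fit$beta$estimate[1]), ybar, tolerance = 1e-8)
})

test_that("ML and REML give the grand mean on balanced intercept-only data", {
  df <- balanced_oneway(20, 4, seed = 4)
  for (method in c("ML", "REML")) {
    fit <- fit_lmm(df, lmm_spec(response = "y", fixed_terms = character(0),
                                method = method, cov_structure = "IND"))
    expect_equal(unname(fit$beta$estimate[1]), mean(df$y), tolerance = 1e-8)
  }
})

test_that("the reported ML log-likelihood matches a direct Gaussian density", {
  co <- small_cohort(n = 40, seed = 21)
  for (structure in c("IND", "CS", "AR1")) {
    fit <- fit_lmm(co, lmm_spec(fixed_terms = c("time", "alcohol"),
                                cov_structure = structure, method = "ML"))
    df <- merge(co$longitudinal, co$covariates, by = "subject_id")
    df$time <- df$visit_time
    df <- df[order(df$subject_id, df$time), ]
    X <- model.matrix(~ time + alcohol, df)
    beta <- fit$beta$estimate
    ll <- 0
    for (sid in unique(df$subject_id)) {
      sel <- df$subject_id == sid
      V <- marginal_cov(fit, sid)
      r <- df$sqrt_sbp[sel] - as.vector(X[sel, , drop = FALSE] %*% beta)
      ch <- chol(V)
      ll <- ll - 0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(backsolve(ch, r, transpose = TRUE)^2))
    }
    expect_equal(fit$loglik, ll, tolerance = 1e-6)
  }
})

test_that("AIC and BIC identities hold exactly for every structure", {
  co <- small_cohort(n = 40, seed = 22)
  for (structure in c("IND", "CS", "AR1")) {
    fit <- fit_lmm(co, lmm_spec(fixed_terms = "time",
                                cov_structure = structure))
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params,
                 tolerance = 1e-10)
    expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n_obs),
                 tolerance = 1e-10)
    expect_true(all(fit$beta$se > 0))
    expect_true(all(fit$beta$ci_lower < fit$beta$ci_upper))
    expect_true(all(eigen(fit$D, only.values = TRUE)$values >= 0))
  }
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  co <- small_cohort(n = 80, seed = 5)
  fit <- fit_lmm(co, lmm_spec(fixed_terms = c("time", "alcohol",
                                              "family_history"),
                              cov_structure = "IND",
                              random_terms = "intercept", method = "ML"))
  df <- merge(co$longitudinal, co$covariates, by = "subject_id")
  df$time <- df$visit_time
  ref <- nlme::lme(sqrt_sbp ~ time + alcohol + family_history,
                   random = ~ 1 | subject_id, data = df, method = "ML")
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$beta$estimate), unname(nlme::fixef(ref)),
               tolerance = 1e-5)
  expect_equal(unname(fit$sigma_params["sigma_e"]), ref$sigma,
               tolerance = 1e-4)
})

test_that("heterogeneous CS fitted to CS data gives near-equal variances", {
  # 500 subjects x 10 visits of pure random-intercept + iid noise data
  set.seed(31)
  k <- 500; m <- 10
  u <- rnorm(k, 0, 0.7)
  df <- data.frame(subject_id = rep(seq_len(k), each = m),
                   time = rep(seq_len(m) * 3, k))
  df$sqrt_sbp <- 11.7 + rep(u, each = m) + rnorm(k * m, 0, 0.5)
  fit <- fit_lmm(df, lmm_spec(fixed_terms = character(0),
                              cov_structure = "CSH", method = "REML"))
  sds <- fit$sigma_params[grep("^sigma_bin", names(fit$sigma_params))]
  expect_lt(max(sds) / min(sds), 1.2)
})

test_that("HCS is accepted as a synonym of heterogeneous CS", {
  co <- small_cohort(n = 30, seed = 23, visit_spacing = 12)
  f1 <- fit_lmm(co, lmm_spec(fixed_terms = "time", cov_structure = "CSH"))
  f2 <- fit_lmm(co, lmm_spec(fixed_terms = "time", cov_structure = "HCS"))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected with the aliased column named", {
  co <- small_cohort(n = 30, seed = 24)
  df <- merge(co$longitudinal, co$covariates, by = "subject_id")
  df$time <- df$visit_time
  df$alcohol_copy <- df$alcohol
  expect_error(fit_lmm(df, lmm_spec(fixed_terms = c("time", "alcohol",
                                                    "alcohol_copy"))),
               "alcohol_copy")
})

test_that("the generating intercept is covered by its confidence interval", {
  # simulation coverage study (scaled): the 95% CI for beta_0 should cover
  # the generating 11.71 in at least ~90% of replicate fits
  reps <- 40
  hits <- 0
  for (r in seq_len(reps)) {
    co <- generate_cohort(recovery_config(seed = 3000 + r, n_subjects = 120))
    fit <- fit_lmm(co, lmm_spec(fixed_terms = c("time", "family_history",
                                                "smoking"),
                                cov_structure = "IND", method = "REML"))
    hits <- hits + (fit$beta$ci_lower[1] <= 11.71 &&
                      fit$beta$ci_upper[1] >= 11.71)
  }
  expect_gte(hits / reps, 0.875)
})

test_that("unstructured covariance reproduces sample moments on a common grid", {
  # with a saturated mean and full UN residual (no random effect absorbed:
  # UN + intercept is still identified through off-diagonal structure), the
  # implied marginal covariance should be close to the sample covariance
  set.seed(32)
  k <- 300; m <- 4
  u <- rnorm(k, 0, 1)
  df <- data.frame(subject_id = rep(seq_len(k), each = m),
                   time = rep(0:(m - 1) * 3, k))
  df$sqrt_sbp <- 10 + rep(u, each = m) + rnorm(k * m, 0, 0.6)
  fit <- fit_lmm(df, lmm_spec(fixed_terms = character(0),
                              cov_structure = "UN", method = "REML"))
  Y <- matrix(df$sqrt_sbp, nrow = m)
  Vhat <- marginal_cov(fit, 1)
  expect_equal(as.vector(Vhat), as.vector(cov(t(Y))), tolerance = 0.15)
})
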