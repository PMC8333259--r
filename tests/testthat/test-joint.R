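# A tiny fully explicit joint dataset: hand-specified measurements and one
# survival record per subject, used for oracle comparisons.
toy_joint_data <- function() {
  long <- data.frame(subject_id = c(1, 1), visit_time = c(0, 3),
                     sqrt_sbp = c(11.2, 11.8))
  long$sbp <- long$sqrt_sbp^2
  surv <- data.frame(subject_id = 1, time = 14.5, event = 1)
  cov <- data.frame(subject_id = 1,
                    smoking = factor("Yes", levels = c("No", "Yes")))
  structure(list(longitudinal = long, survival = surv, covariates = cov),
            class = "bp_cohort")
}

toy_theta <- function() {
  list(beta = c("(Intercept)" = 11.4, time = 0.02),
       sigma_e = 0.5, sigma_u = 0.8,
       log_lambda = -5, rho = 1.3,
       alpha = c(smokingYes = 0.4), gamma = 0.25)
}

test_that("quadrature matches dense numerical integration on one subject", {
  data <- toy_joint_data()
  th <- toy_theta()
  spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = "time",
                                             cov_structure = "IND"),
                     survival_covariates = "smoking")

  # independent dense-grid oracle, written out from the model densities
  y <- data$longitudinal$sqrt_sbp; tt <- data$longitudinal$visit_time
  Ti <- data$survival$time; delta <- data$survival$event
  integrand <- function(u) {
    mu <- th$beta[1] + th$beta[2] * tt + u
    f_long <- prod(dnorm(y, mu, th$sigma_e))
    haz <- exp(th$log_lambda) * th$rho * Ti^(th$rho - 1) *
      exp(th$alpha[1] + th$gamma * u)
    cumhaz <- exp(th$log_lambda) * Ti^th$rho * exp(th$alpha[1] + th$gamma * u)
    f_surv <- haz^delta * exp(-cumhaz)
    f_long * f_surv * dnorm(u, 0, th$sigma_u)
  }
  grid <- seq(-8 * th$sigma_u, 8 * th$sigma_u, length.out = 1e5 + 1)
  vals <- vapply(grid, integrand, numeric(1))
  h <- diff(grid[1:2])
  oracle <- log(h * (sum(vals) - 0.5 * (vals[1] + vals[length(vals)])))

  ll <- as.numeric(joint_loglik(th, data, spec))
  expect_equal(ll, oracle, tolerance = 1e-6)

  # plain (non-adaptive) quadrature agrees too at moderate node counts
  spec_plain <- spec; spec_plain$adaptive <- FALSE
  spec_plain$quadrature_nodes <- 41L
  expect_equal(as.numeric(joint_loglik(th, data, spec_plain)), oracle,
               tolerance = 1e-6)
})

test_that("the joint likelihood separates at zero association", {
  co <- small_cohort(n = 60, seed = 61)
  spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = c("time",
                                                             "family_history"),
                                             cov_structure = "IND",
                                             method = "ML"),
                     survival_covariates = "family_history")
  lf <- fit_lmm(co, spec$longitudinal)
  wf <- weibull_fit(co, "family_history", "AFT_logtime")
  b <- wf$coefficients$estimate
  th <- list(beta = setNames(lf$beta$estimate, rownames(lf$beta)),
             sigma_e = unname(lf$sigma_params["sigma_e"]),
             sigma_u = unname(lf$varcomp["sigma_u0"]),
             log_lambda = -b[1] * wf$shape, rho = wf$shape,
             alpha = c(family_historyPositive = -b[2] * wf$shape),
             gamma = 0)
  ll <- as.numeric(joint_loglik(th, co, spec))
  expect_equal(ll, lf$loglik + wf$loglik, tolerance = 1e-6)
})

test_that("the quadrature is converged at the default node count", {
  co <- small_cohort(n = 50, seed = 62)
  th <- toy_theta()
  th$alpha <- c(smokingYes = 0.3)
  lls <- vapply(c(7L, 15L, 31L), function(q) {
    spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = "time",
                                               cov_structure = "IND"),
                       survival_covariates = "smoking",
                       quadrature_nodes = q)
    as.numeric(joint_loglik(th, co, spec))
  }, numeric(1))
  expect_lt(abs(lls[2] - lls[3]), 1e-4)
})

test_that("EM ascends from the separate-fit initialization", {
  co <- small_cohort(n = 80, seed = 63)
  spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = c("time", "smoking"),
                                             cov_structure = "IND",
                                             method = "ML"),
                     survival_covariates = "smoking")
  fit <- fit_joint(co, spec, se = FALSE)
  expect_gte(fit$loglik, fit$loglik_init - 1e-8)
  # the initialization point is exactly the separate-fit likelihood sum
  expect_equal(fit$loglik_init,
               fit$separate_loglik$lmm + fit$separate_loglik$weibull,
               tolerance = 1e-6)
  # the EM trace never decreases materially
  expect_true(all(diff(fit$convergence$trace) > -1e-6))
})

test_that("doubling the quadrature nodes barely moves the association", {
  co <- small_cohort(n = 80, seed = 64)
  mk <- function(q) {
    spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = "time",
                                               cov_structure = "IND",
                                               method = "ML"),
                       survival_covariates = "family_history",
                       quadrature_nodes = q)
    fit_joint(co, spec, se = FALSE)$estimates["gamma"]
  }
  expect_lt(abs(mk(15L) - mk(30L)), 1e-3)
})

test_that("initialization at the truth converges quickly on low-noise data", {
  cfg <- recovery_config(seed = 65, n_subjects = 60, sigma_e = 0.05)
  co <- generate_cohort(cfg)
  spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = c("time",
                                                             "family_history",
                                                             "smoking"),
                                             cov_structure = "IND",
                                             method = "ML"),
                     survival_covariates = c("family_history", "smoking"),
                     tol = 1e-6)
  init <- list(beta = c("(Intercept)" = 11.71, time = -0.001,
                        family_historyPositive = 0.235, smokingYes = 0.158),
               sigma_e = 0.05, sigma_u = 0.7,
               log_lambda = -7.07, rho = 1.2,
               alpha = c(family_historyPositive = 0.549, smokingYes = 0.312),
               gamma = 0.03)
  fit <- fit_joint(co, spec, init = init, se = FALSE)
  expect_lte(fit$convergence$em_iterations, 25)
})

test_that("association test arithmetic and direction", {
  fake <- structure(list(estimates = c(gamma = 0.03), se = c(gamma = 0.0038)),
                    class = "joint_fit")
  at <- association_test(fake)
  expect_equal(round(at$z, 3), 7.895)
  expect_match(at$direction, "higher risk")

  fake0 <- structure(list(estimates = c(gamma = 0), se = c(gamma = 0.5)),
                     class = "joint_fit")
  at0 <- association_test(fake0)
  expect_equal(at0$z, 0)
  expect_equal(at0$p_value, 1)

  fake_na <- structure(list(estimates = c(gamma = 0.1), se = c(gamma = NA)),
                       class = "joint_fit")
  expect_error(association_test(fake_na), "missing")
})

test_that("conditional survival starts at one, decreases, matches quadrature", {
  co <- small_cohort(n = 40, seed = 66)
  spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = "time",
                                             cov_structure = "IND",
                                             method = "ML"),
                     survival_covariates = "smoking")
  fit <- fit_joint(co, spec, se = FALSE)
  sid <- co$survival$subject_id[5]
  tt <- c(0, 5, 10, 20, 40)
  s <- conditional_survival(tt, sid, fit, co)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 0))
  expect_error(conditional_survival(-1, sid, fit, co), "non-negative")

  # closed form against direct numerical integration of the hazard
  th <- fit$theta
  u <- fit$posterior$mode[fit$posterior$subject_id == sid]
  i <- which(co$survival$subject_id == sid)
  w <- as.numeric(co$covariates$smoking[match(sid, co$covariates$subject_id)] == "Yes")
  hz <- function(s) exp(th$log_lambda) * th$rho * s^(th$rho - 1) *
    exp(th$alpha[1] * w + th$gamma * u)
  s_num <- exp(-integrate(hz, 0, 20, rel.tol = 1e-12)$value)
  expect_equal(s[4], s_num, tolerance = 1e-8)
})

test_that("current-value association changes the likelihood as expected", {
  co <- small_cohort(n = 40, seed = 67)
  th <- toy_theta()
  th$alpha <- c(smokingYes = 0.3)
  base <- lmm_spec(fixed_terms = "time", cov_structure = "IND")
  s_sh <- joint_spec(longitudinal = base, survival_covariates = "smoking",
                     association = "shared_intercept")
  s_cv <- joint_spec(longitudinal = base, survival_covariates = "smoking",
                     association = "current_value")
  ll_sh <- as.numeric(joint_loglik(th, co, s_sh))
  ll_cv <- as.numeric(joint_loglik(th, co, s_cv))
  expect_false(isTRUE(all.equal(ll_sh, ll_cv)))
  # at gamma = 0 the two association forms coincide
  th0 <- th; th0$gamma <- 0
  expect_equal(as.numeric(joint_loglik(th0, co, s_sh)),
               as.numeric(joint_loglik(th0, co, s_cv)), tolerance = 1e-8)
})

test_that("Wald and likelihood-ratio assessments of gamma usually agree", {
  # under a null association: LRT statistic 2*(joint - separate fits), since
  # at gamma = 0 the joint likelihood factorizes into the separate fits
  agree <- 0; reps <- 20
  for (r in seq_len(reps)) {
    co <- generate_cohort(recovery_config(seed = 700 + r, n_subjects = 100,
                                          gamma_assoc = 0))
    spec <- joint_spec(longitudinal = lmm_spec(fixed_terms = c("time",
                                                               "family_history"),
                                               cov_structure = "IND",
                                               method = "ML"),
                       survival_covariates = "family_history")
    fit <- fit_joint(co, spec)
    wald_rej <- association_test(fit)$p_value < 0.05
    lf <- fit_lmm(co, spec$longitudinal)
    wf <- weibull_fit(co, "family_history")
    lrt <- 2 * (fit$loglik - (lf$loglik + wf$loglik))
    lrt_rej <- pchisq(max(lrt, 0), 1, lower.tail = FALSE) < 0.05
    agree <- agree + (wald_rej == lrt_rej)
  }
  expect_gte(agree / reps, 0.9)
})

test_that("random-slope longitudinal specs are rejected up front", {
  expect_error(joint_spec(longitudinal = lmm_spec(random_terms = "intercept_slope")),
               "random-intercept")
})
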