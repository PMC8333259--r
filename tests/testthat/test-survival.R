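test_that("product-limit estimate matches the hand-computed toy", {
  km <- km_estimate(km_toy())
  tab <- km$curves[["all"]]
  # events at 1, 3, 4 with risk sets 4, 2, 1
  expect_equal(tab$time[tab$events > 0], c(1, 3, 4))
  ev <- tab[tab$events > 0, ]
  expect_equal(ev$survival, c(0.75, 0.375, 0), tolerance = 1e-12)
  expect_equal(ev$at_risk, c(4, 2, 1))
  expect_equal(unname(km$median["all"]), 3)
  expect_true(km$median_defined["all"])
})

test_that("all-censored data give a flat curve with undefined median", {
  df <- data.frame(time = c(2, 5, 7), event = c(0, 0, 0))
  km <- km_estimate(df)
  expect_true(all(km$curves[["all"]]$survival == 1))
  expect_false(km$median_defined["all"])
  expect_true(is.na(km$median["all"]))
})

test_that("without censoring the KM curve is the empirical survival function", {
  df <- data.frame(time = 1:10, event = rep(1, 10))
  km <- km_estimate(df)
  tab <- km$curves[["all"]]
  expect_equal(tab$survival, 1 - (1:10) / 10, tolerance = 1e-12)
  # and agrees with the independent product-limit computation
  hand <- km_by_hand(df$time, df$event)
  expect_equal(tab$survival, hand$survival, tolerance = 1e-12)
})

test_that("an empty group is rejected by name", {
  df <- data.frame(time = c(1, 2), event = c(1, 1),
                   g = factor(c("a", "a"), levels = c("a", "b")))
  expect_error(km_estimate(df, group = "g"), "b")
})

test_that("log-rank is zero for identical groups and symmetric in labels", {
  base <- data.frame(time = c(3, 5, 8, 11), event = c(1, 0, 1, 1))
  df <- rbind(cbind(base, g = "x"), cbind(base, g = "y"))
  lr <- logrank_test(df, "g")
  expect_lt(lr$chi_square, 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-6)

  toy <- logrank_toy()
  lr1 <- logrank_test(toy, "grp")
  toy$grp <- factor(ifelse(toy$grp == "a", "b", "a"))
  lr2 <- logrank_test(toy, "grp")
  expect_equal(lr1$chi_square, lr2$chi_square, tolerance = 1e-12)

  expect_error(logrank_test(data.frame(time = 1:3, event = c(1, 1, 0),
                                       g = "only"), "g"),
               "two")
})

test_that("log-rank matches the brute-force observed-expected tabulation", {
  toy <- logrank_toy()
  lr <- logrank_test(toy, "grp")
  oracle <- logrank_by_hand(toy$time, toy$event, toy$grp)
  expect_equal(lr$chi_square, oracle$chi_square, tolerance = 1e-10)
  expect_equal(lr$p_value, oracle$p_value, tolerance = 1e-10)

  # and on a bigger random instance
  set.seed(51)
  df <- data.frame(time = rexp(60, 0.1), event = rbinom(60, 1, 0.7),
                   g = factor(sample(c("a", "b"), 60, TRUE)))
  expect_equal(logrank_test(df, "g")$chi_square,
               logrank_by_hand(df$time, df$event, df$g)$chi_square,
               tolerance = 1e-8)
})

test_that("Cox estimate matches a grid search over the partial likelihood", {
  df <- data.frame(time = c(2, 4, 5, 7, 9), event = c(1, 1, 0, 1, 1),
                   x = c(1, 0, 1, 1, 0))
  fit <- cox_fit(df, "x")
  grid <- seq(-3, 3, by = 1e-4)
  pl <- vapply(grid, cox_partial_loglik, numeric(1),
               time = df$time, event = df$event, x = df$x)
  expect_equal(unname(fit$coefficients$estimate[1]), grid[which.max(pl)],
               tolerance = 1e-4)
  expect_equal(fit$loglik, max(pl), tolerance = 1e-6)
  expect_equal(fit$loglik_null,
               cox_partial_loglik(0, df$time, df$event, df$x),
               tolerance = 1e-10)
})

test_that("a constant covariate is dropped and leaves the null likelihood", {
  df <- data.frame(time = c(2, 4, 5, 7, 9), event = c(1, 1, 0, 1, 1),
                   x = c(1, 0, 1, 1, 0), z = 0)
  expect_warning(fit <- cox_fit(df, c("x", "z")), "dropped")
  expect_false("z" %in% rownames(fit$coefficients))
  df2 <- data.frame(time = df$time, event = df$event, z = 0)
  expect_warning(fit2 <- cox_fit(df2, "z"), "dropped")
  expect_equal(fit2$loglik, fit2$loglik_null, tolerance = 1e-10)
})

test_that("Cox recovers a generating log-hazard ratio", {
  set.seed(52)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.05 * exp(0.7 * x))
  cens <- rexp(n, rate = 0.02)
  df <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                   x = x)
  fit <- cox_fit(df, "x")
  expect_lt(abs(fit$coefficients$estimate[1] - 0.7),
            2.5 * fit$coefficients$se[1])
})

test_that("PH log-time interaction test is quiet under PH and loud without", {
  set.seed(53)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  # proportional hazards: constant hazard ratio
  t_ev <- rexp(n, 0.05 * exp(0.5 * x))
  df <- data.frame(time = pmin(t_ev, 30), event = as.integer(t_ev <= 30),
                   x = x)
  ph <- ph_test(df, "x")
  expect_gt(ph$table$p_value[1], 0.01)
  expect_equal(ph$global$df[[1]], 1)

  # hazard ratio that decays over time: early strong effect, none later
  set.seed(54)
  rate1 <- ifelse(x == 1, 0.25, 0.05)
  t1 <- rexp(n, rate1)
  t_pw <- ifelse(t1 <= 5, t1, 5 + rexp(n, 0.05))
  df2 <- data.frame(time = pmin(t_pw, 40), event = as.integer(t_pw <= 40),
                    x = x)
  ph2 <- ph_test(df2, "x")
  expect_lt(ph2$global$p_value[[1]], 0.05)
})

test_that("Weibull at fixed shape 1 reduces to the exponential MLE", {
  set.seed(55)
  df <- data.frame(time = rexp(200, 0.1), event = 1)
  fit <- weibull_fit(df, parameterization = "AFT_logtime", shape_fixed = 1)
  expect_equal(fit$shape, 1, tolerance = 1e-10)
  rate_mle <- sum(df$event) / sum(df$time)
  expect_equal(exp(-fit$coefficients$estimate[1]), rate_mle,
               tolerance = 1e-6)
})

test_that("AFT and PH parameterizations obey the exact conversion identity", {
  co <- small_cohort(n = 150, seed = 56)
  ph <- weibull_fit(co, c("family_history", "smoking"), "PH_loghazard")
  aft <- weibull_fit(co, c("family_history", "smoking"), "AFT_logtime")
  expect_equal(ph$coefficients$estimate,
               -aft$coefficients$estimate * ph$shape, tolerance = 1e-10)
  expect_equal(ph$shape, aft$shape, tolerance = 1e-12)
  expect_equal(ph$ratios, exp(ph$coefficients$estimate), tolerance = 1e-12)
  # the alternate table carried by each fit is the other parameterization
  expect_equal(ph$alt_coefficients$estimate, aft$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("Weibull recovery within two standard errors", {
  set.seed(57)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  rho <- 1.5; lam <- 0.005; a <- 0.6
  t_ev <- (rexp(n) / (lam * exp(a * x)))^(1 / rho)
  cens <- rexp(n, 1 / 40)
  df <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                   x = x)
  expect_gt(mean(df$event), 0.5)
  fit <- weibull_fit(df, "x", "PH_loghazard")
  expect_lt(abs(fit$shape - rho), 2 * fit$shape_se)
  expect_lt(abs(fit$coefficients["x", "estimate"] - a),
            2 * fit$coefficients["x", "se"])
})

test_that("all-censored data and zero-event data are rejected", {
  df <- data.frame(time = c(3, 6, 9), event = 0)
  expect_error(weibull_fit(df), "censored")
  expect_error(cox_fit(df, "time"), "event")
})

test_that("ratio tables exponentiate estimates and interval bounds", {
  fake <- list(coefficients = data.frame(
    estimate = c(0.549, 0.312, 0), se = c(0.1833, 0.156, 0.1),
    z_value = NA, p_value = NA,
    row.names = c("family_historyPositive", "smokingYes", "null")))
  rt <- ratio_table(fake)
  expect_equal(round(rt$ratio, 3), c(1.732, 1.366, 1))
  expect_equal(rt$ci_lower, exp(fake$coefficients$estimate -
                                  qnorm(0.975) * fake$coefficients$se),
               tolerance = 1e-12)
  expect_true(all(rt$ci_lower < rt$ci_upper))
})
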