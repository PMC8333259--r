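## Survival analysis under right censoring: Kaplan-Meier curves, log-rank
## tests, Cox proportional hazards with a log(time)-interaction diagnostic,
## and parametric Weibull regression reported in both the accelerated
## failure time (AFT) and proportional hazards (PH) parameterizations.
## Estimation is delegated to the survival package; this module defines the
## result containers, the parameterization conversions and the reporting.

surv_frame <- function(data) {
  if (inherits(data, "bp_cohort"))
    merge(data$survival, data$covariates, by = "subject_id")
  else as.data.frame(data)
}

#' Kaplan-Meier estimate with median survival time
#'
#' Product-limit estimator of the survival function, overall or per group.
#' The median is the smallest time at which the estimated survival drops to
#' 0.5 or below; when the curve never reaches 0.5 the median is `NA` and
#' flagged as undefined.
#'
#' @param data a `"bp_cohort"` or a data.frame with columns `time` (months,
#'   positive) and `event` (0 = censored, 1 = death).
#' @param group optional name of a grouping column.
#' @return an object of class `"km_curve"`: a list of per-group tables
#'   `(time, at_risk, events, survival)` plus `median` and
#'   `median_defined` per group.
#' @export
km_estimate <- function(data, group = NULL) {
  df <- surv_frame(data)
  stopifnot(all(df$time > 0), all(df$event %in% c(0, 1)))
  if (is.null(group)) {
    df$.group <- factor("all")
  } else {
    if (!group %in% names(df))
      stop(sprintf("grouping column '%s' not found", group), call. = FALSE)
    df$.group <- if (is.factor(df[[group]])) df[[group]]
                 else factor(df[[group]])
  }
  empty <- setdiff(levels(df$.group), unique(as.character(df$.group)))
  if (length(empty))
    stop(sprintf("empty group(s): %s", paste(empty, collapse = ", ")),
         call. = FALSE)
  curves <- list(); median <- c(); median_defined <- c()
  for (g in levels(df$.group)) {
    sub <- df[df$.group == g, ]
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    tab <- data.frame(time = sf$time, at_risk = sf$n.risk,
                      events = sf$n.event, survival = sf$surv)
    curves[[g]] <- tab
    hit <- which(tab$survival <= 0.5 & tab$events > 0)
    if (length(hit)) {
      median[g] <- tab$time[hit[1]]; median_defined[g] <- TRUE
    } else {
      median[g] <- NA_real_; median_defined[g] <- FALSE
    }
  }
  structure(list(curves = curves, median = median,
                 median_defined = median_defined, group = group),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier estimate",
      if (!is.null(x$group)) sprintf("by %s", x$group) else "", "\n")
  for (g in names(x$curves)) {
    med <- if (x$median_defined[g]) sprintf("%.1f months", x$median[g])
           else "not reached"
    cat(sprintf("  %s: %d event times, median survival %s\n", g,
                nrow(x$curves[[g]]), med))
  }
  invisible(x)
}

#' Log-rank test for equality of survival curves
#'
#' Observed-minus-expected event counts with hypergeometric variance summed
#' over event times, referred to a chi-square distribution on
#' (number of groups - 1) degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group name of the grouping column (at least two non-empty groups).
#' @return an object of class `"logrank_result"` with `chi_square`, `df`,
#'   `p_value`.
#' @export
logrank_test <- function(data, group) {
  df <- surv_frame(data)
  df$.group <- factor(df[[group]])
  df$.group <- droplevels(df$.group)
  if (nlevels(df$.group) < 2)
    stop("the log-rank test requires at least two non-empty groups",
         call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ .group, data = df)
  df_free <- nlevels(df$.group) - 1
  structure(list(chi_square = sd_$chisq, df = df_free,
                 p_value = stats::pchisq(sd_$chisq, df_free,
                                         lower.tail = FALSE),
                 group = group),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test by %s: chi-square = %.3f on %d df, p = %.4g\n",
              x$group, x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional hazards regression
#'
#' Maximizes the log partial likelihood (Breslow handling of ties) by
#' Newton-Raphson and reports the coefficient table and the partial
#' log-likelihood. Monotone likelihood (perfect separation) is detected and
#' reported as an error naming the suspect covariate.
#'
#' @inheritParams km_estimate
#' @param covariates character vector of covariate column names.
#' @return an object of class `"cox_fit"` with `coefficients` (estimate, SE,
#'   z, p), `loglik` (partial log-likelihood at the optimum), `loglik_null`,
#'   and the underlying `survival::coxph` object.
#' @export
cox_fit <- function(data, covariates) {
  df <- surv_frame(data)
  if (sum(df$event) < 1)
    stop("at least one event is required", call. = FALSE)
  form <- stats::reformulate(covariates,
                             response = "survival::Surv(time, event)")
  fit <- survival::coxph(form, data = df, ties = "breslow")
  co <- summary(fit)$coefficients
  dropped <- rownames(co)[is.na(co[, "coef"])]
  if (length(dropped)) {
    warning(sprintf("constant/aliased covariate term(s) dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    co <- co[!is.na(co[, "coef"]), , drop = FALSE]
  }
  if (nrow(co) &&
      (any(!is.finite(co[, "se(coef)"])) || any(abs(co[, "coef"]) > 15))) {
    worst <- rownames(co)[which.max(abs(co[, "coef"]))]
    stop(sprintf("monotone partial likelihood (perfect separation); inspect covariate '%s'",
                 worst), call. = FALSE)
  }
  tab <- data.frame(estimate = co[, "coef"], se = co[, "se(coef)"],
                    z_value = co[, "z"], p_value = co[, "Pr(>|z|)"],
                    row.names = rownames(co))
  structure(list(coefficients = tab, loglik = fit$loglik[2],
                 loglik_null = fit$loglik[1], model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional hazards fit (Breslow ties); partial logLik %.3f (null %.3f)\n",
              x$loglik, x$loglik_null))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Proportional-hazards assumption test via log(time) interactions
#'
#' For each covariate, extends the Cox model with the time-dependent term
#' `covariate x log(t)` and reports the 1-df Wald chi-square for the
#' interaction (indicator covariates with several levels contribute a joint
#' Wald test on their interaction block). The global test refits the model
#' with every interaction simultaneously and tests the full interaction
#' block. Small interaction p-values indicate hazard ratios that change with
#' time, i.e. a PH violation.
#'
#' @inheritParams cox_fit
#' @return an object of class `"ph_test"` with `table`
#'   `(covariate, chi_sq, df, p_value)` and `global` `(chi_sq, df, p_value)`.
#' @export
ph_test <- function(data, covariates) {
  df <- surv_frame(data)
  ttfun <- function(x, t, ...) {
    if (is.factor(x) || is.character(x)) {
      mm <- stats::model.matrix(~ x, data.frame(x = x))[, -1, drop = FALSE]
      mm * log(t)
    } else x * log(t)
  }
  block_wald <- function(fit, pattern) {
    co <- stats::coef(fit)
    sel <- grep(pattern, names(co))
    b <- co[sel]
    Vb <- stats::vcov(fit)[sel, sel, drop = FALSE]
    chi <- as.numeric(t(b) %*% solve(Vb, b))
    c(chi = chi, df = length(sel))
  }
  rows <- vector("list", length(covariates))
  for (k in seq_along(covariates)) {
    cv <- covariates[k]
    form <- stats::as.formula(paste0("survival::Surv(time, event) ~ ",
                                     paste(covariates, collapse = " + "),
                                     " + tt(", cv, ")"))
    fit <- survival::coxph(form, data = df, ties = "breslow", tt = ttfun,
                           control = survival::coxph.control(iter.max = 50))
    w <- block_wald(fit, "^tt\\(")
    rows[[k]] <- data.frame(covariate = cv, chi_sq = w["chi"], df = w["df"],
                            p_value = stats::pchisq(w["chi"], w["df"],
                                                    lower.tail = FALSE))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  gform <- stats::as.formula(paste0("survival::Surv(time, event) ~ ",
                                    paste(covariates, collapse = " + "), " + ",
                                    paste(sprintf("tt(%s)", covariates),
                                          collapse = " + ")))
  gfit <- survival::coxph(gform, data = df, ties = "breslow", tt = ttfun,
                          control = survival::coxph.control(iter.max = 50))
  gw <- block_wald(gfit, "^tt\\(")
  structure(list(table = tab,
                 global = data.frame(chi_sq = gw["chi"], df = gw["df"],
                                     p_value = stats::pchisq(gw["chi"], gw["df"],
                                                             lower.tail = FALSE),
                                     row.names = "global")),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, digits = 4, ...) {
  cat("Proportional-hazards assessment (covariate x log(time) interactions)\n")
  print(cbind(x$table[1], round(x$table[-1], digits)), row.names = FALSE)
  cat("Global:\n")
  print(round(x$global, digits))
  invisible(x)
}

#' Weibull survival regression
#'
#' Maximum likelihood fit of the Weibull model for right-censored times,
#' `sum(delta * log f(t) + (1 - delta) * log S(t))`, via Newton-type
#' iterations (survival::survreg). Results are reported in a declared
#' parameterization: `"AFT_logtime"` (coefficients act on log survival time)
#' or `"PH_loghazard"` (coefficients act on the log hazard), linked by the
#' exact identity `beta_PH = -beta_AFT * shape`. The intercept converts
#' alongside the covariate coefficients; the PH baseline is
#' `lambda = exp(-intercept_AFT * shape)`.
#'
#' @inheritParams cox_fit
#' @param parameterization `"PH_loghazard"` (default, hazard-ratio reading)
#'   or `"AFT_logtime"`.
#' @param shape_fixed optional fixed positive shape; `shape_fixed = 1` gives
#'   the exponential model.
#' @return an object of class `"weibull_fit"` with `shape` (rho), a
#'   coefficient table (estimate, SE, z, p) in the requested
#'   parameterization, `ratios = exp(estimate)`, the coefficients of the
#'   other parameterization in `alt_coefficients`, and `loglik`.
#' @export
weibull_fit <- function(data, covariates = NULL,
                        parameterization = c("PH_loghazard", "AFT_logtime"),
                        shape_fixed = NULL) {
  parameterization <- match.arg(parameterization)
  df <- surv_frame(data)
  if (sum(df$event) < 1)
    stop("all observations are censored: the Weibull shape is not identifiable",
         call. = FALSE)
  form <- if (length(covariates))
    stats::reformulate(covariates, response = "survival::Surv(time, event)")
  else stats::as.formula("survival::Surv(time, event) ~ 1")
  if (!is.null(shape_fixed)) {
    stopifnot(shape_fixed > 0)
    fit <- survival::survreg(form, data = df, dist = "weibull",
                             scale = 1 / shape_fixed)
  } else {
    fit <- survival::survreg(form, data = df, dist = "weibull")
    degenerate <- !is.finite(fit$scale) || fit$scale < 1e-4 ||
      fit$scale > 1e4 || any(!is.finite(stats::coef(fit)))
    if (degenerate) {
      # restart from the exponential solution; the free fit can collapse to
      # scale ~ 0 from survreg's default starting values
      fe <- survival::survreg(form, data = df, dist = "exponential")
      fit <- survival::survreg(form, data = df, dist = "weibull",
                               init = stats::coef(fe), scale = 0)
      if (!is.finite(fit$scale) || fit$scale < 1e-4 || fit$scale > 1e4)
        stop("Weibull fit failed to converge to a non-degenerate shape",
             call. = FALSE)
    }
  }
  shape <- 1 / fit$scale
  b_aft <- stats::coef(fit)
  V <- stats::vcov(fit)  # includes Log(scale) as the last parameter
  p <- length(b_aft)
  if (nrow(V) == p)  # fixed shape: no Log(scale) row
    V <- rbind(cbind(V, 0), 0)
  logsc <- log(fit$scale)

  # delta method for beta_PH = -beta_AFT * exp(-log_scale)
  se_aft <- sqrt(diag(V)[seq_len(p)])
  grad_se_ph <- function(j) {
    g <- numeric(p + 1)
    g[j] <- -exp(-logsc)
    g[p + 1] <- b_aft[j] * exp(-logsc)
    sqrt(as.numeric(t(g) %*% V %*% g))
  }
  b_ph <- -b_aft * shape
  se_ph <- vapply(seq_len(p), grad_se_ph, numeric(1))

  make_tab <- function(b, se) {
    z <- b / se
    data.frame(estimate = b, se = se, z_value = z,
               p_value = 2 * stats::pnorm(-abs(z)), row.names = names(b_aft))
  }
  tab_aft <- make_tab(b_aft, se_aft)
  tab_ph <- make_tab(b_ph, se_ph)
  tab <- if (parameterization == "PH_loghazard") tab_ph else tab_aft
  alt <- if (parameterization == "PH_loghazard") tab_aft else tab_ph

  structure(list(shape = shape, shape_se = shape * sqrt(diag(V)[p + 1]),
                 coefficients = tab, parameterization = parameterization,
                 ratios = exp(tab$estimate),
                 alt_coefficients = alt,
                 alt_parameterization = setdiff(c("PH_loghazard", "AFT_logtime"),
                                                parameterization),
                 loglik = fit$loglik[2], model = fit),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Weibull regression (%s parameterization); shape rho = %.4f, logLik %.3f\n",
              x$parameterization, x$shape, x$loglik))
  tab <- cbind(round(x$coefficients, digits),
               `exp(coef)` = round(x$ratios, 3))
  print(tab)
  invisible(x)
}

#' Hazard/time ratios with confidence intervals
#'
#' Elementwise exponential of a fitted coefficient table and of its 95\%
#' Wald confidence bounds. Under the PH parameterization the ratios are
#' hazard ratios (values above 1 mean higher death risk); under AFT they are
#' time ratios.
#'
#' @param fit a `"weibull_fit"` (or `"cox_fit"`).
#' @param level confidence level (default 0.95).
#' @return a data.frame `(estimate, se, z_value, p_value, ratio, ci_lower,
#'   ci_upper)` with the CI on the ratio scale.
#' @export
ratio_table <- function(fit, level = 0.95) {
  tab <- fit$coefficients
  crit <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(tab,
             ratio = exp(tab$estimate),
             ci_lower = exp(tab$estimate - crit * tab$se),
             ci_upper = exp(tab$estimate + crit * tab$se),
             row.names = rownames(tab))
}
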