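## Synthetic cohort generation: linked longitudinal and survival processes.
##
## The longitudinal process is a Gaussian random-intercept model on the
## square-root SBP scale; the survival process is Weibull proportional
## hazards with hazard
##   lambda(t) = exp(log_lambda) * rho * t^(rho - 1) * exp(x'alpha + gamma * link),
## where link = u_i (shared intercept) or m_i(t) (current latent value).

# Evaluate "covariate:Level" indicator effects against a covariate table.
indicator_lp <- function(covariates, effects) {
  eta <- numeric(nrow(covariates))
  nms <- setdiff(names(effects), c("(Intercept)", "time"))
  for (nm in nms) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(covariates))
      stop(sprintf("effect '%s' does not match any covariate column", nm),
           call. = FALSE)
    eta <- eta + effects[[nm]] * (as.character(covariates[[parts[1]]]) == parts[2])
  }
  eta
}

#' Generate baseline covariates for a synthetic cohort
#'
#' Draws one row per subject. Each categorical covariate is sampled
#' independently from its category probabilities; baseline fasting blood
#' sugar (`fbs`) is log-normal.
#'
#' @param config a [synthetic_config()].
#' @return a data.frame with `subject_id`, one factor column per categorical
#'   covariate (levels in configured order, first level = reference), and
#'   numeric `fbs`.
#' @export
generate_covariates <- function(config) {
  validate_config(config)
  n <- config$n_subjects
  out <- data.frame(subject_id = seq_len(n))
  for (nm in names(config$covariate_prevalences)) {
    p <- config$covariate_prevalences[[nm]]
    out[[nm]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                        levels = names(p))
  }
  out$fbs <- stats::rlnorm(n, meanlog = config$fbs_meanlog,
                           sdlog = config$fbs_sdlog)
  out
}

#' Generate longitudinal sqrt-SBP trajectories
#'
#' Visits are scheduled every `visit_spacing` months from baseline, jittered
#' uniformly by `+/- visit_jitter` (baseline is not jittered), and truncated
#' at each subject's follow-up time. The measurement at time t is
#' `x'beta + beta_time * t + u_i + e`, with `e ~ N(0, sigma_e^2)`; SBP is its
#' square. A draw that would make sqrt-SBP negative is resampled (the count
#' of resampled draws is attached as attribute `"n_resampled"` and reported
#' via a message).
#'
#' @param covariates covariate table from [generate_covariates()] (one row
#'   per subject, `subject_id` column).
#' @param random_intercept numeric vector of subject random intercepts
#'   (sqrt-mmHg), one per row of `covariates`.
#' @param followup numeric vector of follow-up times (months) at which each
#'   subject's measurement schedule stops.
#' @param config a [synthetic_config()].
#' @return long-format data.frame `(subject_id, visit_time, sbp, sqrt_sbp)`.
#' @export
generate_trajectory <- function(covariates, random_intercept, followup, config) {
  validate_config(config)
  n <- nrow(covariates)
  stopifnot(length(random_intercept) == n, length(followup) == n)
  eta0 <- config$beta_long[["(Intercept)"]] +
    indicator_lp(covariates, config$beta_long) + random_intercept
  slope <- if ("time" %in% names(config$beta_long))
    config$beta_long[["time"]] else 0

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- seq(0, followup[i], by = config$visit_spacing)
    if (length(tt) > 1 && config$visit_jitter > 0) {
      jit <- stats::runif(length(tt) - 1, -config$visit_jitter,
                          config$visit_jitter)
      tt[-1] <- pmin(pmax(tt[-1] + jit, 0), followup[i])
      tt <- sort(tt)
    }
    rows[[i]] <- data.frame(subject_id = covariates$subject_id[i],
                            visit_time = tt)
  }
  long <- do.call(rbind, rows)
  idx <- match(long$subject_id, covariates$subject_id)
  mu <- eta0[idx] + slope * long$visit_time
  eps <- stats::rnorm(nrow(long), 0, config$sigma_e)
  n_resampled <- 0L
  bad <- which(mu + eps < 0)
  while (length(bad)) {
    n_resampled <- n_resampled + length(bad)
    eps[bad] <- stats::rnorm(length(bad), 0, config$sigma_e)
    bad <- bad[mu[bad] + eps[bad] < 0]
  }
  if (n_resampled > 0)
    message(sprintf("generate_trajectory: resampled %d negative sqrt-SBP draw(s)",
                    n_resampled))
  long$sqrt_sbp <- mu + eps
  long$sbp <- long$sqrt_sbp^2
  long <- long[c("subject_id", "visit_time", "sbp", "sqrt_sbp")]
  rownames(long) <- NULL
  attr(long, "n_resampled") <- n_resampled
  long
}

# Cumulative hazard at time t given covariate linear predictor eta
# (= x'alpha + gamma*u for shared_intercept) and, for current_value,
# the time-varying exponent gamma * beta_time * s handled by the caller.
weibull_cumhaz <- function(t, log_lambda, rho, eta) {
  exp(log_lambda + eta) * t^rho
}

#' Generate linked event and censoring times
#'
#' Event times follow the Weibull proportional-hazards model with hazard
#' multiplier `exp(gamma * u_i)` (shared intercept; inverse-transform
#' sampling in closed form) or `exp(gamma * m_i(t))` (current latent value;
#' numerical inversion of the cumulative hazard). Censoring is the minimum
#' of an exponential time and the administrative limit `max_followup`;
#' `event = 1` iff death precedes censoring.
#'
#' @inheritParams generate_trajectory
#' @return data.frame `(subject_id, time, event)` with `time` in months and
#'   `event` in `{0, 1}`.
#' @export
generate_event_time <- function(covariates, random_intercept, config) {
  validate_config(config)
  n <- nrow(covariates)
  stopifnot(length(random_intercept) == n)
  rho <- config$weibull_shape
  xalpha <- indicator_lp(covariates, config$alpha_surv)
  e <- stats::rexp(n)  # unit-exponential targets for Lambda(T)

  if (config$association == "shared_intercept") {
    eta <- xalpha + config$gamma_assoc * random_intercept
    death <- (e / exp(config$log_lambda + eta))^(1 / rho)
  } else {
    # m_i(t) = x'beta + beta_time * t + u_i on the sqrt-SBP scale
    m0 <- config$beta_long[["(Intercept)"]] +
      indicator_lp(covariates, config$beta_long) + random_intercept
    slope <- if ("time" %in% names(config$beta_long))
      config$beta_long[["time"]] else 0
    g <- config$gamma_assoc
    death <- numeric(n)
    for (i in seq_len(n)) {
      base <- exp(config$log_lambda + xalpha[i] + g * m0[i])
      cumhaz <- function(t)
        base * stats::integrate(function(s) rho * s^(rho - 1) * exp(g * slope * s),
                                0, t, rel.tol = 1e-10)$value
      upper <- config$max_followup * 4
      while (cumhaz(upper) < e[i] && upper < 1e6) upper <- upper * 4
      if (cumhaz(upper) < e[i]) {
        death[i] <- upper  # beyond any follow-up; will be censored
      } else {
        root <- tryCatch(
          stats::uniroot(function(t) cumhaz(t) - e[i], c(1e-12, upper),
                         tol = 1e-10)$root,
          error = function(err)
            stop(sprintf("numerical inversion of the cumulative hazard failed for subject %s: %s",
                         covariates$subject_id[i], conditionMessage(err)),
                 call. = FALSE))
        death[i] <- root
      }
    }
  }

  cens <- if (config$censoring_rate > 0)
    pmin(stats::rexp(n, config$censoring_rate), config$max_followup)
  else rep(config$max_followup, n)
  data.frame(subject_id = covariates$subject_id,
             time = pmin(death, cens),
             event = as.integer(death <= cens))
}

#' Generate a complete synthetic cohort
#'
#' Runs the covariate, random-effect, survival and trajectory generators in a
#' fixed order under the configured seed, so that identical configurations
#' yield identical cohorts. Longitudinal visits are truncated at each
#' subject's observed (event or censoring) time.
#'
#' @param config a [synthetic_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return an object of class `"bp_cohort"`: a list with components
#'   `longitudinal` (long-format measurements), `survival` (one row per
#'   subject: `subject_id`, `time`, `event`), `covariates` (one row per
#'   subject), and `truth` (the generating config and the per-subject random
#'   intercepts).
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  covariates <- generate_covariates(config)
  u <- stats::rnorm(config$n_subjects, 0, config$sigma_u)
  surv <- generate_event_time(covariates, u, config)
  long <- generate_trajectory(covariates, u, surv$time, config)
  structure(list(longitudinal = long, survival = surv,
                 covariates = covariates,
                 truth = list(config = config, random_intercept = u)),
            class = "bp_cohort")
}

#' @export
print.bp_cohort <- function(x, ...) {
  n <- nrow(x$survival)
  cat(sprintf("Synthetic hypertension cohort: %d subjects, %d measurements\n",
              n, nrow(x$longitudinal)))
  cat(sprintf("  deaths: %d (%.1f%%); follow-up: median %.1f, max %.1f months\n",
              sum(x$survival$event), 100 * mean(x$survival$event),
              stats::median(x$survival$time), max(x$survival$time)))
  cat(sprintf("  visits per subject: median %.0f (range %d-%d)\n",
              stats::median(table(x$longitudinal$subject_id)),
              min(table(x$longitudinal$subject_id)),
              max(table(x$longitudinal$subject_id))))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes `longitudinal.csv` (`subject_id, visit_time, sbp, sqrt_sbp`),
#' `survival.csv` (`subject_id, time, event` plus one column per covariate;
#' times in months, `event` coded 1 = death, 0 = censored), and, when the
#' cohort carries a truth block, `truth.yaml` with the generating
#' configuration and random intercepts.
#'
#' @param cohort a `"bp_cohort"`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$longitudinal, file.path(dir, "longitudinal.csv"),
                   row.names = FALSE)
  surv <- merge(cohort$survival, cohort$covariates, by = "subject_id")
  surv <- surv[order(surv$subject_id), ]
  utils::write.csv(surv, file.path(dir, "survival.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    cfg <- cohort$truth$config
    cfg_list <- unclass(cfg)
    cfg_list$beta_long <- as.list(cfg$beta_long)
    cfg_list$alpha_surv <- as.list(cfg$alpha_surv)
    cfg_list$covariate_prevalences <-
      lapply(cfg$covariate_prevalences, as.list)
    yaml::write_yaml(list(config = cfg_list,
                          random_intercept = cohort$truth$random_intercept),
                     file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `longitudinal.csv` and `survival.csv`
#'   (and optionally `truth.yaml`).
#' @return a `"bp_cohort"`.
#' @export
read_cohort <- function(dir) {
  long <- utils::read.csv(file.path(dir, "longitudinal.csv"))
  surv_full <- utils::read.csv(file.path(dir, "survival.csv"),
                               check.names = FALSE)
  truth <- NULL
  prev <- NULL
  tf <- file.path(dir, "truth.yaml")
  if (file.exists(tf)) {
    raw <- yaml::read_yaml(tf)
    cfg_list <- raw$config
    cfg_list$beta_long <- unlist(cfg_list$beta_long)
    cfg_list$alpha_surv <- unlist(cfg_list$alpha_surv)
    cfg_list$covariate_prevalences <-
      lapply(cfg_list$covariate_prevalences, unlist)
    cfg <- do.call(synthetic_config, cfg_list[names(cfg_list) %in%
                                                names(formals(synthetic_config))])
    truth <- list(config = cfg,
                  random_intercept = unlist(raw$random_intercept))
    prev <- cfg$covariate_prevalences
  }
  surv <- surv_full[c("subject_id", "time", "event")]
  cov_cols <- setdiff(names(surv_full), c("time", "event"))
  covariates <- surv_full[cov_cols]
  for (nm in names(covariates)) {
    if (!is.null(prev) && nm %in% names(prev)) {
      covariates[[nm]] <- factor(covariates[[nm]], levels = names(prev[[nm]]))
    } else if (is.character(covariates[[nm]])) {
      covariates[[nm]] <- factor(covariates[[nm]])
    }
  }
  structure(list(longitudinal = long, survival = surv,
                 covariates = covariates, truth = truth),
            class = "bp_cohort")
}
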