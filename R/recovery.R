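#' Parameter-recovery simulation study for the joint model
#'
#' Repeatedly generates cohorts from [recovery_config()] (318 subjects,
#' ~11\% deaths, association gamma = 0.03) and refits the generating joint
#' model, collecting estimates and standard errors for the key parameters:
#' the trajectory intercept, the variance components, the Weibull shape, the
#' survival covariate effects and the association parameter.
#'
#' @param reps number of replicate cohorts.
#' @param seed integer; replicate r uses seed `seed * 1000 + r`.
#' @param n_subjects cohort size per replicate.
#' @param gamma_assoc generating association parameter.
#' @param quadrature_nodes Gauss-Hermite nodes per fit.
#' @return a data.frame with one row per replicate: columns `est_*` and
#'   `se_*` for `beta0`, `sigma_u`, `sigma_e`, `rho`, `alpha_fh`,
#'   `alpha_smoke`, `gamma`, plus `events` and `converged`. The generating
#'   values are attached as attribute `"truth"`.
#' @export
recovery_study <- function(reps = 200, seed = 1L, n_subjects = 318,
                           gamma_assoc = 0.03, quadrature_nodes = 15L) {
  spec <- joint_spec(
    longitudinal = lmm_spec(fixed_terms = c("time", "family_history",
                                            "smoking"),
                            cov_structure = "IND", random_terms = "intercept",
                            method = "ML"),
    survival_covariates = c("family_history", "smoking"),
    quadrature_nodes = quadrature_nodes)
  keys <- c(beta0 = "(Intercept)", sigma_u = "sigma_u", sigma_e = "sigma_e",
            rho = "rho", gamma = "gamma")
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- recovery_config(seed = seed * 1000 + r, n_subjects = n_subjects,
                           gamma_assoc = gamma_assoc)
    co <- generate_cohort(cfg)
    fit <- tryCatch(fit_joint(co, spec), error = function(e) NULL)
    if (is.null(fit)) {
      rows[[r]] <- data.frame(rep = r, converged = FALSE)
      next
    }
    out <- data.frame(rep = r, converged = TRUE,
                      events = sum(co$survival$event))
    for (nm in names(keys)) {
      i <- match(keys[[nm]], fit$param_names)
      if (nm %in% c("beta0")) i <- 1L
      out[[paste0("est_", nm)]] <- fit$estimates[[i]]
      out[[paste0("se_", nm)]] <- fit$se[[i]]
    }
    # survival coefficients sit after (beta, sigmas, log_lambda, rho)
    py <- length(fit$theta$beta)
    a_idx <- py + 4 + seq_along(fit$theta$alpha)
    out$est_alpha_fh <- fit$estimates[[a_idx[1]]]
    out$se_alpha_fh <- fit$se[[a_idx[1]]]
    out$est_alpha_smoke <- fit$estimates[[a_idx[2]]]
    out$se_alpha_smoke <- fit$se[[a_idx[2]]]
    rows[[r]] <- out
  }
  res <- do.call(rbind, lapply(rows, function(x) {
    miss <- setdiff(c("rep", "converged", "events",
                      paste0("est_", c(names(keys), "alpha_fh", "alpha_smoke")),
                      paste0("se_", c(names(keys), "alpha_fh", "alpha_smoke"))),
                    names(x))
    for (m in miss) x[[m]] <- NA_real_
    x
  }))
  attr(res, "truth") <- c(beta0 = 11.71, sigma_u = 0.7, sigma_e = 0.5,
                          rho = 1.2, alpha_fh = 0.549, alpha_smoke = 0.312,
                          gamma = gamma_assoc)
  res
}
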