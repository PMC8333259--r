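## Model selection and screening procedures for the longitudinal sub-model:
## residual covariance structure selection by AIC, random-effect
## configuration selection, univariable screening at a modest significance
## level, and the normality/transformation check for the response.

#' Compare residual covariance structures by information criteria
#'
#' Fits the same mixed model under each candidate residual covariance
#' structure and tabulates AIC, BIC and log-likelihood. The selected
#' structure is the AIC minimizer; ties preserve input order (stable sort).
#' A structure that fails to fit is reported in its row rather than aborting
#' the comparison.
#'
#' @param data as in [fit_lmm()].
#' @param base_spec an [lmm_spec()]; its `cov_structure` is replaced by each
#'   candidate in turn.
#' @param structures character vector of structures to compare.
#' @return a data.frame of class `"lmm_selection"` sorted by AIC with
#'   columns `structure`, `aic`, `bic`, `loglik`, `n_params`, `error`;
#'   attribute `"selected"` holds the winning structure and `"fits"` the
#'   fitted objects.
#' @export
compare_cov_structures <- function(data, base_spec = lmm_spec(),
                                   structures = c("IND", "CS", "AR1", "CSH", "UN")) {
  rows <- vector("list", length(structures))
  fits <- vector("list", length(structures))
  for (k in seq_along(structures)) {
    sp <- base_spec
    sp$cov_structure <- match.arg(structures[k], LMM_STRUCTURES)
    f <- tryCatch(fit_lmm(data, sp), error = function(e) e)
    if (inherits(f, "error")) {
      rows[[k]] <- data.frame(structure = structures[k], aic = NA_real_,
                              bic = NA_real_, loglik = NA_real_,
                              n_params = NA_integer_,
                              error = conditionMessage(f))
    } else {
      fits[[k]] <- f
      rows[[k]] <- data.frame(structure = structures[k], aic = f$aic,
                              bic = f$bic, loglik = f$loglik,
                              n_params = f$n_params, error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  names(fits) <- structures
  ord <- order(tab$aic)  # stable; NAs last
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "selected") <- tab$structure[which.min(tab$aic)]
  attr(tab, "fits") <- fits
  class(tab) <- c("lmm_selection", "data.frame")
  tab
}

#' Compare random-effect configurations by information criteria
#'
#' As [compare_cov_structures()], but varying the random-effect terms over
#' `{intercept, slope, intercept_slope}` with the residual structure held
#' fixed.
#'
#' @inheritParams compare_cov_structures
#' @param configurations random-effect configurations to compare.
#' @return a data.frame of class `"lmm_selection"` (column `random_terms`).
#' @export
compare_random_effects <- function(data, base_spec = lmm_spec(),
                                   configurations = c("intercept", "slope",
                                                      "intercept_slope")) {
  rows <- vector("list", length(configurations))
  fits <- vector("list", length(configurations))
  for (k in seq_along(configurations)) {
    sp <- base_spec
    sp$random_terms <- match.arg(configurations[k], LMM_RANDOM)
    f <- tryCatch(fit_lmm(data, sp), error = function(e) e)
    if (inherits(f, "error")) {
      rows[[k]] <- data.frame(random_terms = configurations[k],
                              aic = NA_real_, bic = NA_real_,
                              loglik = NA_real_, n_params = NA_integer_,
                              error = conditionMessage(f))
    } else {
      fits[[k]] <- f
      rows[[k]] <- data.frame(random_terms = configurations[k], aic = f$aic,
                              bic = f$bic, loglik = f$loglik,
                              n_params = f$n_params, error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  names(fits) <- configurations
  ord <- order(tab$aic)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "selected") <- tab$random_terms[which.min(tab$aic)]
  attr(tab, "fits") <- fits
  class(tab) <- c("lmm_selection", "data.frame")
  tab
}

#' @export
print.lmm_selection <- function(x, digits = 2, ...) {
  cat("Model selection by AIC (selected:", attr(x, "selected"), ")\n")
  print.data.frame(cbind(x[1], round(x[c("aic", "bic", "loglik")], digits),
                         x["n_params"]), row.names = FALSE)
  invisible(x)
}

#' Univariable screening of longitudinal covariates
#'
#' Fits, for each candidate covariate, a random-intercept mixed model
#' containing only the visit time and that covariate, and retains candidates
#' whose Wald test (joint over the covariate's indicator columns) has
#' p-value below `alpha`. The conventional screening level is a modest 0.25
#' so that potentially relevant covariates survive to the multivariable
#' model.
#'
#' @param data as in [fit_lmm()].
#' @param candidates character vector of covariate column names.
#' @param alpha screening level in (0, 1].
#' @param spec an [lmm_spec()] providing response, method and residual
#'   structure for the marginal models; its fixed terms are replaced by
#'   `time + candidate`.
#' @return a data.frame `(covariate, df, chi_sq, p_value, retained)`;
#'   attribute `"retained"` is the character vector of retained covariates.
#'   Constant covariates are excluded with a warning.
#' @export
univariable_screen <- function(data, candidates, alpha = 0.25,
                               spec = lmm_spec(cov_structure = "IND")) {
  stopifnot(alpha > 0, alpha <= 1)
  df0 <- lmm_frame(data)
  rows <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    cand <- candidates[k]
    if (!cand %in% names(df0))
      stop(sprintf("candidate covariate '%s' not found", cand), call. = FALSE)
    v <- df0[[cand]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning(sprintf("covariate '%s' is constant and was excluded from the screen",
                      cand), call. = FALSE)
      rows[[k]] <- data.frame(covariate = cand, df = NA_integer_,
                              chi_sq = NA_real_, p_value = NA_real_,
                              retained = FALSE)
      next
    }
    sp <- spec
    sp$fixed_terms <- c("time", cand)
    f <- fit_lmm(df0, sp)
    sel <- grep(paste0("^", cand), rownames(f$beta))
    b <- f$beta$estimate[sel]
    Vb <- f$vcov_beta[sel, sel, drop = FALSE]
    chi <- as.numeric(t(b) %*% solve(Vb, b))
    pv <- stats::pchisq(chi, df = length(sel), lower.tail = FALSE)
    rows[[k]] <- data.frame(covariate = cand, df = length(sel), chi_sq = chi,
                            p_value = pv, retained = pv < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "retained") <- out$covariate[which(out$retained)]
  out
}

#' Normality check with transformation recommendation
#'
#' Computes Shapiro-Wilk and Kolmogorov-Smirnov (Lilliefors: KS against the
#' Gaussian with estimated mean and SD) p-values for the raw values and their
#' square-root and natural-log transforms, and recommends the first transform
#' in the order none, sqrt, log for which both tests have p > 0.05 (or the
#' one with the largest minimum p-value if none qualifies).
#'
#' Shapiro-Wilk is limited to 5000 values; larger samples are thinned to
#' 5000 evenly spaced order statistics.
#'
#' When `design` is supplied (a model matrix or data.frame of covariates),
#' each transform is residualized on it by least squares before testing, so
#' the check targets the Gaussian-error assumption of a regression model
#' rather than marginal normality — with strong covariate effects the
#' marginal distribution is a mixture and no transform can look Gaussian.
#'
#' @param values numeric vector of at least 20 positive values.
#' @param design optional model matrix or data.frame (one row per value)
#'   whose fixed effects are removed before testing.
#' @return list with `table` (a 3 x 2 data.frame of p-values) and
#'   `recommendation` (`"none"`, `"sqrt"`, or `"log"`).
#' @export
check_normality <- function(values, design = NULL) {
  keep <- !is.na(values)
  values <- values[keep]
  if (length(values) < 20)
    stop("at least 20 values are required", call. = FALSE)
  if (any(values <= 0))
    stop("values must be strictly positive for the sqrt and log transforms",
         call. = FALSE)
  adjust <- identity
  if (!is.null(design)) {
    X <- if (is.data.frame(design)) stats::model.matrix(~ ., design[keep, , drop = FALSE])
         else design[keep, , drop = FALSE]
    adjust <- function(x) stats::lsfit(X, x, intercept = FALSE)$residuals + mean(x)
  }
  thin <- function(x) {
    if (length(x) <= 5000) return(x)
    sort(x)[round(seq(1, length(x), length.out = 5000))]
  }
  transforms <- list(none = adjust(values), sqrt = adjust(sqrt(values)),
                     log = adjust(log(values)))
  tab <- data.frame(shapiro_p = rep(NA_real_, 3), ks_p = rep(NA_real_, 3),
                    row.names = names(transforms))
  for (nm in names(transforms)) {
    x <- transforms[[nm]]
    tab[nm, "shapiro_p"] <- stats::shapiro.test(thin(x))$p.value
    tab[nm, "ks_p"] <- nortest::lillie.test(x)$p.value
  }
  ok <- tab$shapiro_p > 0.05 & tab$ks_p > 0.05
  rec <- if (any(ok)) rownames(tab)[which(ok)[1]]
         else rownames(tab)[which.max(pmin(tab$shapiro_p, tab$ks_p))]
  list(table = tab, recommendation = rec)
}
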