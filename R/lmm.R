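## Linear mixed-effects models for sqrt-SBP with structured residual
## covariance, fitted by maximizing the profiled Gaussian marginal
## (restricted) likelihood:
##   Y_i ~ N(X_i beta, V_i),  V_i = Z_i D Z_i' + Sigma_i.
## beta is profiled out by GLS; the variance parameters are optimized on an
## unconstrained scale (log standard deviations, Fisher-z correlations,
## log-Cholesky factors). The Woodbury identity keeps every per-subject solve
## at the cost of the residual structure plus a q x q system (q <= 2), and
## subjects sharing a visit pattern are processed as one matrix operation.

LMM_STRUCTURES <- c("IND", "CS", "CSH", "AR1", "UN", "HCS")
LMM_RANDOM <- c("intercept", "slope", "intercept_slope")

#' Specify a linear mixed model for longitudinal sqrt-SBP
#'
#' @param response name of the response column (default `"sqrt_sbp"`).
#' @param fixed_terms character vector of fixed-effect terms; `"time"`
#'   refers to the visit time in months. An intercept is always included.
#' @param random_terms one of `"intercept"`, `"slope"`,
#'   `"intercept_slope"`.
#' @param cov_structure residual covariance structure, one of `"IND"`
#'   (independent), `"CS"` (compound symmetry), `"CSH"` (heterogeneous
#'   compound symmetry), `"AR1"` (first-order autoregressive over the visit
#'   index), `"UN"` (unstructured over the scheduled visit grid), or
#'   `"HCS"` (treated as a synonym of `"CSH"`).
#' @param method `"REML"` or `"ML"`.
#' @param grid_spacing months between scheduled visits, used only to bin
#'   visit times for the `CSH`/`UN` structures; inferred from the data when
#'   `NULL`.
#' @return an object of class `"lmm_spec"`.
#' @export
lmm_spec <- function(response = "sqrt_sbp",
                     fixed_terms = "time",
                     random_terms = c("intercept", "slope", "intercept_slope"),
                     cov_structure = LMM_STRUCTURES,
                     method = c("REML", "ML"),
                     grid_spacing = NULL) {
  random_terms <- match.arg(random_terms)
  cov_structure <- match.arg(cov_structure)
  method <- match.arg(method)
  if (length(fixed_terms) == 0)
    fixed_terms <- character(0)
  structure(list(response = response, fixed_terms = fixed_terms,
                 random_terms = random_terms, cov_structure = cov_structure,
                 method = method, grid_spacing = grid_spacing),
            class = "lmm_spec")
}

# Merge the longitudinal records of a cohort with its covariate table and
# expose `time` as a column. Accepts a bp_cohort or a prepared data.frame.
lmm_frame <- function(data) {
  if (inherits(data, "bp_cohort")) {
    df <- merge(data$longitudinal, data$covariates, by = "subject_id")
  } else {
    df <- as.data.frame(data)
  }
  if (!"time" %in% names(df) && "visit_time" %in% names(df))
    df$time <- df$visit_time
  df[order(df$subject_id, df$time), , drop = FALSE]
}

# ---- variance-parameter transforms -----------------------------------------

# random-effect parameter count and D builders
re_npar <- function(random_terms) switch(random_terms,
  intercept = 1L, slope = 1L, intercept_slope = 3L)

re_build <- function(random_terms, th) {
  if (random_terms %in% c("intercept", "slope")) {
    s2 <- exp(2 * th[1])
    list(D = matrix(s2, 1, 1), Dinv = matrix(1 / s2, 1, 1),
         logdetD = 2 * th[1], q = 1L)
  } else {
    L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
    D <- L %*% t(L)
    list(D = D, Dinv = chol2inv(chol(D)), logdetD = 2 * (th[1] + th[3]),
         q = 2L)
  }
}

res_npar <- function(structure, B) switch(structure,
  IND = 1L, CS = 2L, AR1 = 2L, CSH = B + 1L, UN = B * (B + 1L) / 2L)

# Residual covariance matrix for one visit pattern.
# bins: integer visit-bin labels (CSH/UN); n: number of visits.
res_sigma <- function(structure, th, n, bins, B) {
  switch(structure,
    IND = diag(exp(2 * th[1]), n),
    CS = {
      s2 <- exp(2 * th[1]); r <- tanh(th[2])
      s2 * ((1 - r) * diag(n) + r * matrix(1, n, n))
    },
    AR1 = {
      s2 <- exp(2 * th[1]); r <- tanh(th[2])
      s2 * r^abs(outer(seq_len(n), seq_len(n), "-"))
    },
    CSH = {
      s <- exp(th[seq_len(B)]); r <- tanh(th[B + 1])
      sv <- s[bins]
      R <- (1 - r) * diag(n) + r * matrix(1, n, n)
      outer(sv, sv) * R
    },
    UN = {
      L <- matrix(0, B, B)
      L[lower.tri(L, diag = TRUE)] <- th
      diag(L) <- exp(diag(L))
      Psi <- L %*% t(L)
      Psi[bins, bins, drop = FALSE]
    })
}

# natural-scale summary of the residual parameters
res_natural <- function(structure, th, B, bin_labels) {
  switch(structure,
    IND = c(sigma_e = exp(th[1])),
    CS = c(sigma_e = exp(th[1]), rho = tanh(th[2])),
    AR1 = c(sigma_e = exp(th[1]), rho = tanh(th[2])),
    CSH = stats::setNames(c(exp(th[seq_len(B)]), tanh(th[B + 1])),
                          c(paste0("sigma_bin", bin_labels), "rho")),
    UN = {
      L <- matrix(0, B, B)
      L[lower.tri(L, diag = TRUE)] <- th
      diag(L) <- exp(diag(L))
      Psi <- L %*% t(L)
      v <- Psi[lower.tri(Psi, diag = TRUE)]
      idx <- which(lower.tri(Psi, diag = TRUE), arr.ind = TRUE)
      stats::setNames(v, paste0("psi_", bin_labels[idx[, 1]], "_",
                                bin_labels[idx[, 2]]))
    })
}

# ---- data layout ------------------------------------------------------------

# Group subjects by visit pattern and precompute the stacked matrices used by
# the likelihood. X: N x p model matrix (rows sorted subject-major).
lmm_layout <- function(df, X, y, structure, grid_spacing) {
  ids <- df$subject_id
  t_all <- df$time
  usub <- unique(ids)
  n_i <- as.integer(table(factor(ids, levels = usub)))

  needs_bins <- structure %in% c("CSH", "UN")
  if (needs_bins) {
    if (is.null(grid_spacing)) {
      gaps <- unlist(tapply(t_all, factor(ids, levels = usub),
                            function(v) diff(sort(v))))
      gaps <- gaps[gaps > 0]
      if (!length(gaps))
        stop("cannot infer the visit grid: no within-subject time gaps",
             call. = FALSE)
      grid_spacing <- stats::median(gaps)
    }
    bin <- as.integer(round(t_all / grid_spacing)) + 1L
    dup <- tapply(bin, factor(ids, levels = usub),
                  function(b) any(duplicated(b)))
    if (any(dup))
      stop(sprintf("subject %s has duplicate visits in the same grid bin; %s requires one visit per scheduled time",
                   usub[which(dup)[1]], structure), call. = FALSE)
    bin_labels <- sort(unique(bin))
    bin <- match(bin, bin_labels)  # compact 1..B
    B <- length(bin_labels)
  } else {
    bin <- rep(1L, length(ids)); bin_labels <- 1L; B <- max(n_i)
  }

  row_of <- split(seq_along(ids), factor(ids, levels = usub))
  key <- vapply(seq_along(usub), function(i) {
    r <- row_of[[i]]
    if (needs_bins) paste(bin[r], collapse = ",") else as.character(length(r))
  }, character(1))

  patterns <- lapply(split(seq_along(usub), key), function(sub_idx) {
    r1 <- row_of[[sub_idx[1]]]
    n <- length(r1); m <- length(sub_idx); p <- ncol(X)
    rows <- unlist(row_of[sub_idx])
    Xrows <- X[rows, , drop = FALSE]
    arr <- array(Xrows, dim = c(n, m, p))
    list(n = n, m = m, sub_idx = sub_idx,
         bins = bin[r1],
         Y = matrix(y[rows], n, m),
         Tm = matrix(t_all[rows], n, m),
         Xcat = matrix(aperm(arr, c(1, 3, 2)), n, p * m),
         Xflat = Xrows)
  })

  list(patterns = patterns, N = length(ids), p = ncol(X),
       n_subjects = length(usub), subjects = usub, n_i = n_i,
       B = if (needs_bins) B else max(n_i),
       bin_labels = if (needs_bins) bin_labels else seq_len(max(n_i)),
       grid_spacing = grid_spacing)
}

# ---- likelihood kernel ------------------------------------------------------

# Profiled (negative) log-likelihood and the GLS pieces at given variance
# parameters. Returns a list or a large penalty on a non-PD proposal.
lmm_kernel <- function(theta, layout, spec, want_blups = FALSE) {
  nre <- re_npar(spec$random_terms)
  re <- re_build(spec$random_terms, theta[seq_len(nre)])
  resth <- theta[-seq_len(nre)]
  structure_ <- if (spec$cov_structure == "HCS") "CSH" else spec$cov_structure
  q <- re$q
  p <- layout$p

  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  yVy <- 0; logdet <- 0
  pat_cache <- vector("list", length(layout$patterns))

  for (k in seq_along(layout$patterns)) {
    pt <- layout$patterns[[k]]
    n <- pt$n; m <- pt$m
    Sg <- res_sigma(structure_, resth, n, pt$bins, layout$B)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Si <- chol2inv(ch)
    if (any(!is.finite(Si))) return(NULL)
    logdetS <- 2 * sum(log(diag(ch)))
    AY <- Si %*% pt$Y
    AX <- Si %*% pt$Xcat
    AXflat <- matrix(aperm(array(AX, c(n, p, m)), c(1, 3, 2)), n * m, p)

    # z'Az, z'AX, z'Ay components for z = 1 and/or z = t
    use1 <- spec$random_terms %in% c("intercept", "intercept_slope")
    uset <- spec$random_terms %in% c("slope", "intercept_slope")
    if (use1) {
      a11 <- rep(sum(Si), m)
      B1 <- t(matrix(colSums(AX), p, m))      # m x p, rows = 1'A X_i
      c1 <- colSums(AY)
    }
    if (uset) {
      AT <- Si %*% pt$Tm
      att <- colSums(pt$Tm * AT)
      Trep <- pt$Tm[, rep(seq_len(m), each = p), drop = FALSE]
      B2 <- t(matrix(colSums(AX * Trep), p, m)) # m x p, rows = t'A X_i
      c2 <- colSums(AY * pt$Tm)
      if (use1) a1t <- colSums(AT)
    }

    XtVX_k <- crossprod(pt$Xflat, AXflat)
    XtVy_k <- crossprod(AXflat, as.vector(pt$Y))
    yVy_k <- sum(pt$Y * AY)

    if (q == 1) {
      if (use1) { av <- a11; Bm <- B1; cv <- c1 } else { av <- att; Bm <- B2; cv <- c2 }
      M <- re$Dinv[1, 1] + av
      if (any(M <= 0)) return(NULL)
      w <- 1 / M
      XtVX_k <- XtVX_k - crossprod(Bm, Bm * w)
      XtVy_k <- XtVy_k - crossprod(Bm, cv * w)
      yVy_k <- yVy_k - sum(cv^2 * w)
      logdet <- logdet + m * (logdetS + re$logdetD) + sum(log(M))
      if (want_blups) pat_cache[[k]] <- list(Bm = Bm, cv = cv, w = w)
    } else {
      m11 <- re$Dinv[1, 1] + a11
      m12 <- re$Dinv[1, 2] + a1t
      m22 <- re$Dinv[2, 2] + att
      detM <- m11 * m22 - m12^2
      if (any(detM <= 0) || any(m11 <= 0)) return(NULL)
      ia <- m22 / detM; ib <- -m12 / detM; ic <- m11 / detM
      XtVX_k <- XtVX_k -
        (crossprod(B1, B1 * ia) + crossprod(B1, B2 * ib) +
           crossprod(B2, B1 * ib) + crossprod(B2, B2 * ic))
      XtVy_k <- XtVy_k -
        (crossprod(B1, ia * c1 + ib * c2) + crossprod(B2, ib * c1 + ic * c2))
      yVy_k <- yVy_k - sum(ia * c1^2 + 2 * ib * c1 * c2 + ic * c2^2)
      logdet <- logdet + m * (logdetS + re$logdetD) + sum(log(detM))
      if (want_blups)
        pat_cache[[k]] <- list(B1 = B1, B2 = B2, c1 = c1, c2 = c2,
                               ia = ia, ib = ib, ic = ic)
    }
    XtVX <- XtVX + XtVX_k
    XtVy <- XtVy + as.vector(XtVy_k)
    yVy <- yVy + yVy_k
  }

  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  beta <- backsolve(chX, backsolve(chX, XtVy, transpose = TRUE))
  quad <- yVy - sum(beta * XtVy)
  if (quad < 0) quad <- 0
  N <- layout$N
  ll <- if (spec$method == "ML") {
    -0.5 * (N * log(2 * pi) + logdet + quad)
  } else {
    -0.5 * ((N - p) * log(2 * pi) + logdet + 2 * sum(log(diag(chX))) + quad)
  }

  out <- list(loglik = ll, beta = beta, XtVX = XtVX, chX = chX, re = re)
  if (want_blups) {
    blups <- matrix(0, layout$n_subjects, q)
    for (k in seq_along(layout$patterns)) {
      pt <- layout$patterns[[k]]; pc <- pat_cache[[k]]
      if (q == 1) {
        resid1 <- pc$cv - as.vector(pc$Bm %*% beta)
        blups[pt$sub_idx, 1] <- resid1 * pc$w
      } else {
        r1 <- pc$c1 - as.vector(pc$B1 %*% beta)
        r2 <- pc$c2 - as.vector(pc$B2 %*% beta)
        blups[pt$sub_idx, 1] <- pc$ia * r1 + pc$ib * r2
        blups[pt$sub_idx, 2] <- pc$ib * r1 + pc$ic * r2
      }
    }
    out$blups <- blups
  }
  out
}

# ---- fitting ---------------------------------------------------------------

#' Fit a linear mixed model by ML or REML
#'
#' Maximizes the Gaussian marginal (restricted) likelihood of
#' `Y_i ~ N(X_i beta, Z_i D Z_i' + Sigma_i)` over the fixed effects and the
#' variance parameters of the chosen random-effect configuration and residual
#' covariance structure. Fixed effects are profiled out by generalized least
#' squares; variance parameters are optimized by quasi-Newton iterations on
#' an unconstrained scale (log standard deviations, Fisher-z correlations,
#' log-Cholesky factors), with random restarts on non-convergence. BLUPs of
#' the random effects are computed at the fitted variance components.
#'
#' Fixed-effect t statistics use residual degrees of freedom
#' (observations minus fixed-effect parameters).
#'
#' @param data a `"bp_cohort"` or a long-format data.frame with columns
#'   `subject_id`, `time` (or `visit_time`), the response, and any fixed-term
#'   columns.
#' @param spec an [lmm_spec()].
#' @return an object of class `"lmm_fit"` with components `beta` (coefficient
#'   table with SE, t, p, 95\% CI), `D`, `varcomp`, `sigma_params`, `loglik`,
#'   `aic`, `bic`, `n_params`, `blups`, `spec`, and convergence information.
#' @export
fit_lmm <- function(data, spec = lmm_spec()) {
  stopifnot(inherits(spec, "lmm_spec"))
  df <- lmm_frame(data)
  if (!spec$response %in% names(df))
    stop(sprintf("response column '%s' not found", spec$response), call. = FALSE)
  y <- df[[spec$response]]
  form <- if (length(spec$fixed_terms))
    stats::reformulate(spec$fixed_terms) else ~1
  X <- stats::model.matrix(form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; aliased column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  n_i <- table(df$subject_id)
  if (length(n_i) < 2)
    stop("at least 2 subjects are required", call. = FALSE)
  if (max(n_i) == 1)
    stop("every subject has a single observation: the random-effect and residual variances are not identifiable (the model reduces to ordinary least squares)",
         call. = FALSE)

  structure_ <- if (spec$cov_structure == "HCS") "CSH" else spec$cov_structure
  layout <- lmm_layout(df, X, y, structure_, spec$grid_spacing)
  nre <- re_npar(spec$random_terms)
  nres <- res_npar(structure_, layout$B)

  # moment-based starting values from the OLS residual variance
  ols <- qr.coef(qrX, y)
  s2 <- sum((y - X %*% ols)^2) / (layout$N - layout$p)
  ls_half <- 0.5 * log(s2 / 2)
  th_re <- switch(spec$random_terms,
    intercept = ls_half,
    slope = ls_half - log(mean(abs(df$time)) + 1),
    intercept_slope = c(ls_half, 0, ls_half - log(mean(abs(df$time)) + 1) - 1))
  th_res <- switch(structure_,
    IND = ls_half,
    CS = c(ls_half, atanh(0.2)),
    AR1 = c(ls_half, atanh(0.2)),
    CSH = c(rep(ls_half, layout$B), atanh(0.2)),
    UN = { v <- numeric(layout$B * (layout$B + 1) / 2)
           L <- matrix(0, layout$B, layout$B)
           diag(L) <- ls_half
           v <- L[lower.tri(L, diag = TRUE)]
           v })
  start <- c(th_re, th_res)

  # a sloped penalty outside |theta| <= 20 (log / Fisher-z scale) keeps the
  # optimizer away from degenerate variance regimes where V overflows
  negll <- function(th) {
    if (any(abs(th) > 20) || any(!is.finite(th)))
      return(1e8 + sum(th[is.finite(th)]^2))
    kr <- lmm_kernel(th, layout, spec)
    if (is.null(kr) || !is.finite(kr$loglik)) return(1e8 + sum(th^2))
    -kr$loglik
  }

  fit <- NULL; trace <- character(0)
  for (attempt in 0:3) {
    st <- if (attempt == 0) start else start + stats::rnorm(length(start), 0, 0.5)
    opt <- tryCatch(
      stats::optim(st, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    trace <- c(trace, sprintf("attempt %d: %s (value %.6f)", attempt,
                              if (is.null(opt)) "error"
                              else paste0("convergence ", opt$convergence),
                              if (is.null(opt)) NA_real_ else opt$value))
    if (!is.null(opt) && opt$convergence == 0 && opt$value < 1e9) {
      fit <- opt; break
    }
    if (!is.null(opt) && is.null(fit) && opt$value < 1e9) fit <- opt
  }
  if (is.null(fit))
    stop(paste(c("LMM optimization failed to converge:", trace),
               collapse = "\n  "), call. = FALSE)

  theta <- fit$par
  kr <- lmm_kernel(theta, layout, spec, want_blups = TRUE)
  beta <- as.vector(kr$beta)
  names(beta) <- colnames(X)
  vcov_beta <- chol2inv(kr$chX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  dfree <- layout$N - layout$p
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), dfree)
  crit <- stats::qt(0.975, dfree)
  beta_table <- data.frame(estimate = beta, se = se, t_value = tval,
                           p_value = pval, ci_lower = beta - crit * se,
                           ci_upper = beta + crit * se)

  nvar <- nre + nres
  n_params <- layout$p + nvar
  ll <- kr$loglik
  varcomp <- switch(spec$random_terms,
    intercept = c(sigma_u0 = sqrt(kr$re$D[1, 1])),
    slope = c(sigma_u1 = sqrt(kr$re$D[1, 1])),
    intercept_slope = c(sigma_u0 = sqrt(kr$re$D[1, 1]),
                        sigma_u1 = sqrt(kr$re$D[2, 2]),
                        cov_u0u1 = kr$re$D[1, 2]))
  blups <- kr$blups
  rownames(blups) <- layout$subjects
  colnames(blups) <- switch(spec$random_terms,
    intercept = "u0", slope = "u1", intercept_slope = c("u0", "u1"))

  structure(list(
    beta = beta_table, vcov_beta = vcov_beta, D = kr$re$D,
    varcomp = varcomp,
    sigma_params = res_natural(structure_, theta[-seq_len(nre)],
                               layout$B, layout$bin_labels),
    theta = theta, loglik = ll,
    aic = -2 * ll + 2 * n_params,
    bic = -2 * ll + n_params * log(layout$N),
    n_params = n_params, n_obs = layout$N, n_subjects = layout$n_subjects,
    df_residual = dfree, blups = blups, spec = spec,
    convergence = list(code = fit$convergence, trace = trace,
                       counts = fit$counts),
    layout = layout
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear mixed model (%s, random %s, residual %s)\n",
              x$spec$method, x$spec$random_terms, x$spec$cov_structure))
  cat(sprintf("  %d observations, %d subjects; logLik %.2f, AIC %.2f, BIC %.2f (%d parameters)\n\n",
              x$n_obs, x$n_subjects, x$loglik, x$aic, x$bic, x$n_params))
  print(round(x$beta, digits))
  cat("\nVariance components:\n")
  print(round(x$varcomp, digits))
  cat("Residual parameters:\n")
  print(round(x$sigma_params, digits))
  invisible(x)
}

# Marginal covariance matrix of one subject's response at the fitted
# parameters (used for independent likelihood reconstruction and checks).
#' Fitted marginal covariance of a subject's measurements
#'
#' @param fit an `"lmm_fit"`.
#' @param subject a subject id present in the fitted data.
#' @return the fitted `n_i x n_i` marginal covariance `Z D Z' + Sigma`.
#' @export
marginal_cov <- function(fit, subject) {
  layout <- fit$layout
  spec <- fit$spec
  structure_ <- if (spec$cov_structure == "HCS") "CSH" else spec$cov_structure
  nre <- re_npar(spec$random_terms)
  for (pt in layout$patterns) {
    j <- match(match(subject, layout$subjects), pt$sub_idx)
    if (!is.na(j)) {
      Sg <- res_sigma(structure_, fit$theta[-seq_len(nre)], pt$n, pt$bins,
                      layout$B)
      Z <- switch(spec$random_terms,
        intercept = matrix(1, pt$n, 1),
        slope = matrix(pt$Tm[, j], pt$n, 1),
        intercept_slope = cbind(1, pt$Tm[, j]))
      return(Z %*% fit$D %*% t(Z) + Sg)
    }
  }
  stop(sprintf("subject %s not found in the fitted data", subject),
       call. = FALSE)
}
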