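# bpjm — joint modeling of longitudinal blood pressure and survival

`bpjm` is an R package for the joint analysis of repeatedly measured
systolic blood pressure (SBP) and time to death in hypertension follow-up
cohorts. It is aimed at biostatisticians and epidemiologists who need the
full workflow behind a shared-random-effect ("shared parameter") joint
model: a synthetic-cohort generator with linked longitudinal and survival
processes, linear mixed models with selectable residual covariance
structures, nonparametric and parametric survival analysis under right
censoring, the joint likelihood itself, and an end-to-end pipeline that
emits every table analog of the standard reporting.

## The model

SBP is modeled on the square-root scale (chosen by a normality check). For
subject *i* at visit time *t<sub>ij</sub>* (months):

- **Longitudinal**: `y_ij = x_ij' beta + u_i + e_ij`, with random intercept
  `u_i ~ N(0, sigma_u^2)` and `e_ij ~ N(0, sigma_e^2)`. `fit_lmm()` covers
  the general `Y_i ~ N(X_i beta, Z_i D Z_i' + Sigma_i)` family with residual
  structures IND, CS, CSH/HCS, AR1, UN and random intercept/slope
  configurations, compared by AIC.
- **Survival**: Weibull proportional hazards,
  `lambda_i(t) = lambda * rho * t^(rho-1) * exp(w_i' alpha)`, reported in
  both the PH and AFT parameterizations (exact identity
  `beta_PH = -beta_AFT * rho`), alongside Kaplan–Meier curves, log-rank
  tests, Cox regression and a log(time)-interaction PH diagnostic.
- **Joint**: the hazard is linked to the trajectory through
  `exp(gamma * u_i)` (shared intercept, default) or `exp(gamma * m_i(t))`
  (current latent value). The marginal likelihood integrates over `u_i` by
  adaptive Gauss–Hermite quadrature; estimation is EM with a quasi-Newton
  polish, and `association_test()` reports the Wald z for `gamma` — the
  direction and strength of the blood-pressure/mortality dependence.

## Worked example

```r
library(bpjm)

# 318 subjects, ~11% deaths, 65-month follow-up; non-zero effects restricted
# to family history and smoking so the fitted model matches the generator
cfg <- recovery_config(seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> Synthetic hypertension cohort: 318 subjects, 4088 measurements
#>   deaths: 34 (10.7%); follow-up: median 37.3, max 65.0 months
#>   visits per subject: median 13 (range 1-22)

fit <- fit_joint(cohort, joint_spec(
  longitudinal = lmm_spec(fixed_terms = c("time", "family_history", "smoking"),
                          cov_structure = "IND", method = "ML"),
  survival_covariates = c("family_history", "smoking")))
round(fit$association, 4)
#>             estimate     se z_value p_value
#> association  -0.3586 0.2501 -1.4342  0.1515
round(unname(fit$estimates[c("(Intercept)", "sigma_u", "sigma_e", "rho")]), 3)
#> [1] 11.744  0.693  0.493  1.031
```

The association row is the quantity of interest: the log-hazard change per
unit of latent sqrt-SBP. The longitudinal parameters are sharp — intercept
11.74 sqrt-mmHg (~138 mmHg), between-subject SD 0.69 and residual SD 0.49,
on top of the generating values (11.71, 0.7, 0.5). The association itself
is estimated with an SE near 0.25 on a single cohort with ~34 deaths, so a
generating `gamma` of 0.03 (here estimated at −0.36, 1.4 SE from truth) is
recoverable only in aggregate across replicate cohorts; the 120-replicate
recovery study in `scripts/acceptance.R` and the vignette's information
analysis quantify exactly what this design can and cannot resolve.

The full workflow — descriptives, transform choice, univariable screens,
covariance/random-effect selection, KM/log-rank, PH assessment, Weibull
and joint fits — runs as one call and logs every decision with the
criterion value that drove it:

```r
report <- run_full_analysis(analysis_config(input = cfg, seed = 7))
report$covariance_selection
report$weibull_ratios
report$association
write_report(report, "analysis_out")   # one CSV per table analog
```

The methods vignette (`vignettes/joint-modeling-methods.Rmd`) documents the
model, the generator's calibration to the emulated cohort's published
margins, the numerical choices, and the design decisions.

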