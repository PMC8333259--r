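---
title: "Joint modeling of longitudinal blood pressure and survival: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modeling of longitudinal blood pressure and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpjm)
```

## The scientific problem

In hypertension follow-up cohorts, systolic blood pressure (SBP) is measured
repeatedly at clinic visits while patients are simultaneously at risk of
death, and the two outcomes are not independent: a patient's underlying
blood-pressure level carries information about their hazard. Analyzing the
two streams separately — a mixed model for the trajectories, a survival
model for the deaths — ignores that dependence and can bias both analyses
(informative dropout on the longitudinal side, measurement error on the
survival side). `bpjm` implements the standard remedy, a shared-random-effect
(shared-parameter) joint model, together with every supporting stage of the
workflow: cohort simulation, trajectory modeling with residual-covariance
selection, nonparametric and parametric survival analysis, and an end-to-end
pipeline.

## Model

**Longitudinal sub-model.** SBP is right-skewed; following the usual
normality check (Shapiro–Wilk and Lilliefors tests on raw, square-root and
log transforms; `check_normality()`), measurements are modeled on the
square-root scale. For subject $i$ at visit time $t_{ij}$ (months),

$$y_{ij} = x_{ij}'\beta + u_i + \varepsilon_{ij}, \qquad
u_i \sim N(0, \sigma_u^2), \quad \varepsilon_{ij} \sim N(0, \sigma_e^2),$$

a random-intercept linear mixed model. `fit_lmm()` fits the more general
family $Y_i \sim N(X_i\beta,\; Z_i D Z_i' + \Sigma_i)$ by ML or REML, with
random intercept, random slope, or both, and residual structures from the
closed set IND, CS, CSH, AR1, UN (HCS is accepted as a synonym of CSH: the
"heterogeneous/homogeneous" naming varies across sources, and CS is exactly
the equal-variance special case of the structure implemented here).
Structures are compared by AIC (`compare_cov_structures()`,
`compare_random_effects()`).

**Survival sub-model.** Death times are right-censored. The parametric
model is Weibull. The package always reports both parameterizations, linked
by the exact identity $\beta_{PH} = -\beta_{AFT}\,\rho$: the
accelerated-failure-time form (coefficients act on log time) and the
proportional-hazards form

$$\lambda_i(t) = \lambda\,\rho\,t^{\rho-1} e^{w_i'\alpha},$$

in which $e^{\alpha_k} > 1$ means higher risk of death. Table-style output
(`weibull_fit()`, `ratio_table()`) defaults to the PH reading, because the
hazard-ratio interpretation ("positive family history carries 1.73 times the
risk") is the one used in this literature even when the model is written as
AFT; the AFT equivalent is carried in the same object. Kaplan–Meier curves,
log-rank tests, Cox regression and a proportional-hazards diagnostic based
on covariate-by-log(time) interactions (not scaled Schoenfeld residuals)
complete the survival toolbox.

**Joint model.** The two sub-models share the random intercept. Conditional
on $u_i$ the processes are independent, and the hazard becomes

$$\lambda_i(t \mid u_i) = \lambda\,\rho\,t^{\rho-1}
  \exp\{w_i'\alpha + \gamma \cdot \mathrm{link}_i(t)\},$$

with two selectable association forms: `shared_intercept`
($\mathrm{link} = u_i$; the default, and the form matching the
shared-parameter framing) and `current_value`
($\mathrm{link} = m_i(t) = x_i(t)'\beta + u_i$, the current latent
sqrt-SBP). The association parameter $\gamma$ is the quantity of interest:
its sign says whether higher latent blood pressure goes with higher death
risk, and `association_test()` reports the Wald $z = \hat\gamma /
SE(\hat\gamma)$ with the correct two-sided normal p-value.

The marginal likelihood integrates each subject's product of conditional
densities over $u_i$. In both association forms the survival factor reduces
to $\exp\{\delta_i\gamma u - K_i e^{\gamma u}\}$ in $u$, so the integrand is
log-concave; the integral is evaluated by adaptive Gauss–Hermite quadrature
centered and scaled at the posterior mode found by a few Newton steps
(plain Gauss–Hermite is available via `adaptive = FALSE` for oracle
comparisons). Estimation is EM — closed-form M-step for
$(\beta, \sigma_e^2, \sigma_u^2)$, quasi-Newton M-step for
$(\log\lambda, \rho, \alpha, \gamma)$ against the posterior node weights —
followed in every fit by a direct quasi-Newton polish of the full joint
log-likelihood, so the reported solution does not depend on where EM
stopped. Standard errors come from the numerically differentiated observed
information (central differences, relative step $10^{-5}$, on the scale
that keeps positive parameters log-transformed, mapped back by the delta
method).

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `quadrature_nodes` | 15 | nodes | log-concave integrands are captured by adaptive GH at 15 nodes; doubling changes the log-likelihood by $<10^{-4}$ and $\hat\gamma$ by $<10^{-3}$ on default cohorts (tested) |
| `tol` | 1e-8 | relative log-lik | EM stopping; the secondary criterion is a maximum parameter change of 1e-4, attainable with quasi-Newton inner steps (1e-6 is not), and the final polish makes the stopping rule immaterial |
| `max_iter` | 200 | EM iterations | ample; with separate-fit initialization EM typically converges in < 20 |
| screening `alpha` | 0.25 | level | the conventional modest univariable screening level, so weak but real predictors survive to the multivariable stage |
| CI level | 95% | | fixed throughout the reporting |

Optimization of the mixed model profiles $\beta$ out by GLS and runs BFGS
on unconstrained transforms (log standard deviations, Fisher-z
correlations, log-Cholesky factors for UN and for the 2-by-2 random-effect
covariance), with up to three jittered restarts on non-convergence and a
sloped penalty outside $|\theta| \le 20$ on the transformed scale — without
the penalty the optimizer can escape to $\sigma_e \to 0$ where the
covariance inverse overflows and rounding error fakes an optimum.
Fixed-effect t statistics use residual degrees of freedom (observations
minus fixed-effect count); this choice is documented rather than derived,
since no degrees-of-freedom method is canonical for these designs.
AR1 correlations apply to the visit index (repeated-measures reading), not
elapsed time; CSH and UN require binning visit times to the scheduled grid
and refuse subjects with two visits in one bin. `n_params` counts fixed
effects plus variance parameters, which reproduces the reported AIC
arithmetic of compound-symmetry fits with 20 parameters.

## The synthetic cohort generator

No patient-level data are distributed with this package, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes, calibrated once to the published cohort summaries and
then frozen:

* **Design**: 318 subjects, administrative censoring at 65 months, visits
  every 3 months with uniform ±0.5-month jitter, truncated at the observed
  event/censoring time.
* **Covariates**: the sixteen predictors of the emulated study (gender,
  residence, age group, alcohol, khat, smoking, stress, hypertension stage,
  lifestyle change, cholesterol, adherence, related disease, family
  history, diabetes, fasting blood sugar, visit time). Printed prevalences
  are used where available (female 0.544, urban 0.6478, age > 50 0.5113,
  stage distribution, family history 0.6446, diabetes 0.6132). Several
  prevalences are not printed but are pinned down by the printed
  within-category death proportions (e.g. a death proportion of 16.176% is
  22/136, giving an alcohol-use prevalence of 136/318); the remainder
  (smoking 0.25, stress 0.35, lifestyle 0.55, adherence-poor 0.45) are
  plausible clinical values chosen once. Fasting blood sugar is log-normal
  with median 100 mg/dL.
* **Trajectories**: the published multivariable estimates serve as the
  generating fixed effects (intercept 11.71 sqrt-mmHg, time slope −0.001
  per month, covariate effects as printed — including two rows whose
  printed confidence intervals are inconsistent with their printed
  estimates; the point estimates are used as given). The variance
  components are not printed; $\sigma_u = 0.7$ and $\sigma_e = 0.5$
  sqrt-mmHg give between- and within-subject SDs of roughly 16 and 12 mmHg
  around 140 mmHg, typical of clinic SBP series.
* **Survival**: Weibull PH with shape $\rho = 1.2$ (mildly increasing
  hazard, standard for chronic-disease mortality), the published
  hazard-style coefficients as $\alpha$, association $\gamma = 0.03$ per
  sqrt-mmHg, exponential censoring with mean 62 months. The baseline rate
  ($\log\lambda = -7.52$) and the censoring mean were calibrated once on a
  200,000-subject simulation to the published margins — 11% deaths, median
  follow-up near 38 months — and frozen. The follow-up SD comes out near
  23 months versus the published 19.97; that residual misfit is a
  consequence of the exponential-censoring choice and was deliberately not
  tuned further.
* **Event sampling**: inverse-transform in closed form under
  `shared_intercept`; under `current_value` the cumulative hazard is
  inverted numerically. Negative sqrt-SBP draws (possible only under
  extreme configurations) are resampled, not truncated, keeping the
  Gaussian residual model honest; occurrences are counted and reported.

What the generator does **not** emulate: missingness mechanisms (none are
reported for the source cohort), within-subject covariate drift
(covariates are baseline-fixed), measurement rounding, or the exact joint
distribution of the real registry's covariates (they are sampled
independently). Passing tests on these cohorts therefore demonstrates
correctness of the estimators under the stated model, not robustness to
real-data pathologies.

`recovery_config()` is the variant used for parameter-recovery studies: it
keeps the cohort conditions (318 subjects, ~11% deaths, $\gamma = 0.03$)
but restricts the non-zero effects to family history and smoking in both
sub-models, with the baseline rate recalibrated ($\log\lambda = -7.07$), so
the fitted model matches the generating one — the standard design for a
recovery simulation.

## Numerical choices and degenerate inputs

* The pipeline's normality stage residualizes each candidate transform on
  the categorical covariates before testing (`check_normality(design = )`):
  with covariate effects as large as the generating ones the *marginal*
  distribution of sqrt-SBP is a Gaussian mixture that no transform can make
  look Gaussian, while the mixed model's actual assumption — Gaussian
  errors given covariates — is what the adjusted test targets (and under
  the generator it correctly selects the square root).
* Ties in the survival data: Breslow for Cox; tied KM event times are
  processed jointly.
* One measurement per subject: the mixed model refuses (variance
  components are not identifiable; the model collapses to OLS).
* Rank-deficient fixed-effect designs: refused, naming the aliased column.
* All-censored survival data: the Weibull shape is not identifiable;
  refused. A degenerate survreg solution (scale collapsing to 0 from its
  default starting values, which happens on a few percent of simulated
  cohorts) is restarted from the exponential fit before giving up.
* Constant covariates: excluded from screens with a warning; dropped from
  Cox fits with a warning.
* The unstructured (UN) residual covariance is excluded from the default
  pipeline candidates: on the default visit grid (~20 scheduled times) it
  would carry 200+ parameters. It remains available explicitly and is
  exercised in the test suite on a coarse grid.
* Joint fits support the random-intercept longitudinal sub-model; a
  random-slope joint model would require two-dimensional adaptive
  quadrature and is out of scope (the spec surface errors informatively).

## Design choices where the design was open

* **AFT versus PH reading.** The source tables are AFT in form but are
  interpreted as hazard ratios (positive coefficients = higher risk). The
  package implements the survival side of the joint model on the
  Weibull-PH scale — the standard shared-parameter formulation — and makes
  every standalone Weibull fit carry both parameterizations with the exact
  conversion identity, so neither reading is lost.
* **Association form.** The latent linkage in the source is ambiguous
  between a shared random effect and the current latent value; both are
  implemented behind `joint_spec(association = ...)`, defaulting to
  `shared_intercept` (closed-form event sampling, exact factorization at
  $\gamma = 0$), and every output records which was used.
* **Two independent screens.** The longitudinal and survival univariable
  screens retain separate covariate sets, and the multivariable stages use
  exactly those sets (tested invariant), rather than their union.
* **PH failure handling.** When the global log(time)-interaction test
  rejects proportional hazards, the pipeline proceeds to the parametric
  Weibull model and records the evidence that triggered the switch.

## Problem sizes used by the test suite

The acceptance-style checks run at the study's scale: 200 replicate joint
fits of 318-subject cohorts for parameter recovery, 2000 and 400 null
replicates for the log-rank and screening type-I rates, and 100 replicates
each for the covariance-structure and random-effect selection
consistency. One replicate joint fit takes about 1.5 s on one CPU; the
full suite runs in well under half an hour.

A note on what recovery can show at this design: with ~35 deaths among 318
subjects and a random-intercept SD of 0.7, the Fisher information for
$\gamma$ gives a per-replicate standard error near 0.25–0.30. The Wald
coverage of $\gamma = 0.03$ is therefore testable, but the *mean* of 200
replicate estimates carries a Monte-Carlo standard error near 0.02 — of
the same order as the target value itself — so a mean-recovery band of
±15% of 0.03 is tighter than the design can resolve. The published SE of
0.0038 for the association would require roughly $10^4$ times the
information this cohort contains, which is one of several printed values
(alongside the inconsistent CI rows and a p-value of 0.034 attached to
z = 7.895) suggesting the source tables should be read qualitatively.
The package reports what the stated design actually delivers.

## Known limitations

Beyond the items above: no left/interval censoring or truncation; no
competing risks; no Bayesian estimation; no dynamic predictions beyond
`conditional_survival()`; no log-logistic or lognormal AFT alternatives;
no generalized (non-Gaussian) mixed models, crossed random effects, or
missing-data imputation.
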