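Package: bpjm
Title: Joint Modeling of Longitudinal Blood Pressure and Survival in
    Hypertension Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of repeatedly measured systolic
    blood pressure and time to death in hypertension follow-up cohorts.
    Provides a synthetic-cohort generator with linked longitudinal and
    survival processes, linear mixed-effects models for square-root
    transformed blood pressure under selectable residual covariance
    structures (independent, compound symmetry, heterogeneous compound
    symmetry, first-order autoregressive, unstructured), nonparametric and
    parametric survival analysis under right censoring (Kaplan-Meier,
    log-rank, Cox, Weibull), and a shared-random-effect joint model whose
    likelihood is maximized by an EM algorithm with adaptive Gauss-Hermite
    quadrature, including a Wald test of the association between the
    latent blood-pressure trajectory and the hazard of death.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nortest,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
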