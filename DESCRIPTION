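Package: doxypk
Title: Population Pharmacokinetics and PK/PD Cutoffs for Oral Doxycycline in Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of doxycycline plasma disposition in pigs
    and Monte Carlo determination of PK/PD susceptibility cutoffs. Implements a
    three-compartment mammillary disposition model with route-specific
    first-order absorption submodels (in-feed under field and laboratory
    conditions, drinking water, stomach tubing), allometric body-weight scaling
    of clearances and deep-compartment volume, non-compartmental analysis,
    hierarchical (Laplace-type) nonlinear mixed-effects estimation with staged
    intravenous-then-oral fitting, AIC covariate search, bootstrap confidence
    intervals, shrinkage and visual predictive checks, and probability of
    target attainment simulation on the fAUC/MIC index yielding PK/PD cutoff
    values for candidate dosing scenarios. A synthetic-trial generator
    emulating the meta-analysis design makes every stage testable without the
    original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
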