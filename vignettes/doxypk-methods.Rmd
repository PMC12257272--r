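---
title: "Methods: population PK of oral doxycycline in pigs and PK/PD cutoffs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of oral doxycycline in pigs and PK/PD cutoffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doxypk)
```

## The model

Doxycycline disposition in the pig is described by a mammillary
three-compartment model with central elimination, parametrised per kg of
body weight by plasma clearance `Cl`, distributional clearances `Cl2`,
`Cl3`, and volumes `Vc`, `V2`, `V3`.  Oral input is first-order from a
depot, with a route-specific rate constant `Ka` and absolute
bioavailability `F` for each of the four modalities of administration:
in-feed under field conditions (`FEED_TLS`), in-feed under laboratory
conditions (`FEED_OTHERS`), solution in drinking water (`SOL_DW`) and
solution by stomach tube (`SOL_TUBING`).  All doses are doxycycline base in
mg/kg; `doxy_base_fraction()` converts from the hyclate, monohydrate or
hydrochloride salts.

The concentration solution is closed-form.  The disposition matrix of a
mammillary model with positive micro-constants has three real, negative,
distinct eigenvalues; we compute them as roots of the cubic characteristic
polynomial (trigonometric method) and obtain the IV bolus curve from the
partial-fraction residues of the Laplace-domain transfer function.  The
oral curve follows by convolution with the exponential input, which turns a
`Ka` equal to an eigenvalue into a removable singularity: the implementation
perturbs such a `Ka` by 1e-7 (relative) with a warning.  If the spectrum is
numerically degenerate (relative eigenvalue spacing below 1e-9) the code
falls back to a matrix-exponential evaluation.  Multi-dose profiles are
superpositions of single-dose solutions; concentrations at a dose time are
post-dose for IV and continuous for oral input.

Body weight enters through a power model with the reference fixed at 50 kg
(close to the population median of 44 kg):
`theta(BW) = theta_pop * (BW/50)^theta_BW`, applied to `Cl` (exponent
0.299), `Cl2` (-0.224), `Cl3` (-0.544) and `V3` (0.376) in the final model.
One published table prints 0.376 L/kg for `V3` at 50 kg, which duplicates
the covariate exponent and is inconsistent with the 10/100-kg values of the
same row under the power model; the package uses 0.536 L/kg at 50 kg, the
value the scaled column entries (0.295 and 0.699) reproduce.  Likewise the
printed 50-kg `Vss` and `MRT` are internally consistent with each other but
not with `Vc + V2 + V3` from the same table, so they are not used as
reference values anywhere.

## Between-subject variability and residual error

Random effects are exponential, `p_i = p_typ(BW_i) * exp(eta_i)`, with
independent (diagonal) per-parameter variances — the source analysis
reports no correlations, and we document independence as an assumption.
Published variability is a CV%; the reporting convention is not stated, so
the package defaults to the lognormal reading
`omega = sqrt(log(1 + (CV/100)^2))` and also supports `omega = CV/100`
(`convention = "direct"` in `bsv_percent_to_omega()` and model loaders).
The two differ by under 10% below an 85% CV, and the PK/PD cutoff results
below are unchanged under either reading.  Individual bioavailabilities
`F * exp(eta)` may exceed 1 and are deliberately not truncated (no
truncation is described for the source model); `cap_F_at_1 = TRUE` exists
for sensitivity analysis.  Residual error is additive plus proportional,
`sd^2 = stdev0^2 + (cmult * pred)^2`, with route-specific parameters.

## Estimation

`pkfit()` maximises an approximate marginal likelihood of the Laplace
class: per subject, the joint log-density of observations and random
effects is maximised over the etas (Newton-type inner optimisation,
warm-started between outer iterations) and corrected by half the
log-determinant of the curvature at the mode.  The approximation is exact
for models linear in the random effects; on a one-subject model with a
single multiplicative random effect it agrees with adaptive numerical
integration of the marginal likelihood to about 1e-4 (relative) for small
random-effect scales, degrading gracefully to about 2e-4 at an omega of 0.7
(this is a unit test).  With all omegas zero the objective reduces exactly to the pooled
extended-least-squares -2 log-likelihood.  The engines of the original
analysis (FOCE ELS, QRPEM) are not reproduced bit-for-bit; equivalence is
claimed only at the level of estimate closeness on synthetic data.

Free parameters are estimated on the log scale (covariate exponents and
the optional categorical-covariate coefficient on the natural scale,
bounded to [-3, 3]) with box constraints spanning 1e-4 to 1e3 times the
initial value.  Initial values for clearance and volumes are derived from a
non-compartmental pass over the IV data.  The outer optimiser is L-BFGS-B
with finite-difference steps of 1e-3 on the transformed scale: the inner
optimisation leaves numerical noise of much smaller magnitude on the
objective, and gradient steps must stay above it (with machine-precision
steps the optimiser stalls far from the optimum — the choice is structural,
not cosmetic).  Non-convergence is flagged in the returned object, never
silent.

The staged design of the source analysis is replicated: `stage = "iv_only"`
fits disposition (and optionally body-weight exponents) to IV data;
`stage = "oral_given_iv"` freezes those thetas and estimates only the oral
`Ka`/`F`, residual terms and requested omegas, re-estimating random effects
jointly.  Observations below the LLOQ are discarded before fitting
(`censor_lloq()`), matching the source protocol of dropping the ~2% BLQ
records rather than a censored-likelihood (M3) treatment.

`covariate_search()` fits the body-weight power term on every subset of the
candidate parameters — all 2^6 = 64 subsets for the full set; the printed
"6^2 = 36" in the source text is taken as a typo for the 64 models it also
mentions — and flags subsets improving AIC by at least 6.635, the p < 0.01
likelihood-ratio equivalent.  Equal AICs rank the smaller subset first.  A
binary health-status covariate on `F` is supported as an exponential term
(`cat_on_F`), mirroring the model the source evaluated and then dropped as
non-significant.  `bootstrap_ci()` resamples subjects with replacement,
stratified by route, and reports percentile intervals; standard errors via
the information matrix are out of scope (the source analysis itself could
not obtain them).  Shrinkage is `100 * (1 - SD(eta_EBE)/omega)` per
parameter and `100 * (1 - SD(IWRES))` for epsilon.  `vpc_check()` simulates
each subject's design (500 replicates by default) and compares observed
quantiles — 10/50/90 or 20/50/80 — with simulated bands per time bin,
merging empty bins leftwards.

## PK/PD cutoff computation

The index is `fAUC/MIC` with the unbound fraction fixed at `fu = 0.31`; its
variability is deliberately excluded, following the source analysis.  The
pharmacodynamic target is 72 h over a 3-day treatment — an average free
concentration equal to the MIC across the course; the murine-literature
alternative of 12.36 h/day is available via `pdt_hours`.  For a linear
model the steady-state AUC over the course is `F * D * days / Cl`
analytically (how the daily dose is split within a day does not change it),
and `fauc_over_mic()` also offers a numerical mode that superposes daily
doses to steady state (lead-in of at least ten half-lives) and integrates
by trapezoid; the two agree within 0.5%.  `pta_curve()` draws 5000
individuals at the scenario body weight from the final model —
population simulation from the fitted model; the source text's mention of
IPRED-based simulation is ambiguous between this and empirical-Bayes
resampling, and we document rather than guess — computes the index per MIC
on the grid {0.0625, 0.125, 0.25, 0.375, 0.5, 1, 2} mg/L, and reports PTA
per MIC, the 1-99% quantile table, and the cutoff: the highest grid MIC
with PTA >= 0.90 (equivalently, whose 10% quantile of the index clears the
target).  Residual error is excluded from the simulated curves by default
(`include_residual` exists for sensitivity).  At the published parameters
the 20 mg/kg/day scenarios reproduce a cutoff of 0.25 mg/L for 10-kg
piglets via both feed (field submodel) and drinking water, with 50-kg
animals on drinking water falling short of 0.25 mg/L.  The source's further
claim that the in-feed cutoff of 0.25 mg/L holds regardless of body weight
does not reproduce at 50/100 kg under the documented diagonal-omega
lognormal reading (PTA at 0.25 mg/L lands just below 90%); the discrepancy
is surfaced here rather than resolved by re-reading the variability
convention, and the well-determined 10-kg scenarios anchor the automated
checks.

## The synthetic-trial generator

`default_trial_designs()` mirrors the analyzable-data-set structure of the
meta-analysis: 57 rich IV profiles across 7 trials (doses 5-10.5 mg/kg),
the 215-profile sparse field trial (2 x 5 mg/kg 12 h apart; samples at the
12-h pre-dose trough and 12.66, 14, 16, 18, 24, 36 h), 50 in-feed
laboratory profiles including the repeated-dosing arms (15 x 5.9 mg/kg
q12h; 8 x 13.3 mg/kg q24h, sampled across the final dosing interval),
30 drinking-water and 28 stomach-tube profiles — 380 in total, about 3,500
observations.  Rich designs use 12 samples over 24 h post-dose, consistent
with the reported 8-15 samples over 12-48 h; the exact per-trial schedules
are not published, so these are the package's own choices.  Body weights
are drawn from a power-transformed uniform on 8.5-101 kg
(`8.5 + 92.5 * U^1.3815`), calibrated once so the median is 44 kg — a plain
log-uniform over that range would have median 29 kg, inconsistent with the
reported median.  Sex (~50/50) and health status (146:66 within the field
trial) are generated as labels without effect, matching the final source
model.  Per-trial LLOQs follow the reported 0.022-0.2 ug/mL; at the
published parameters the default suite censors 4-5% of observations, above
the 2% reported for the real data (the heavy-tailed field-trial
bioavailability pushes many trough samples under the limit) but within the
plausibility band the automated checks accept.  What passing tests on these
data show is that the estimator recovers the generating process under the
published design and variability structure; they cannot show robustness to
assay drift, day effects, model misspecification, or the real trials'
individual dosing records, none of which the generator emulates.

## Numerical choices and scaled-down problem sizes

Tolerances that matter: closed-form profiles match an independent ODE
solution to a relative 1e-6 over 0-72 h (tested on 100 random parameter
sets); trapezoidal AUC at a 0.05-h step over ten half-lives is within 0.5%
of the analytic value; eigenvalue-spacing degeneracy below 1e-9 triggers
the matrix-exponential fallback.  The NCA terminal slope uses the
best-adjusted-R^2 contiguous terminal window of at least three points after
Cmax — the source does not state its selection rule, so this common
convention is documented as ours, not inferred as theirs.  Windows with no
negative-slope fit leave the slope-dependent quantities "not computable"
(`NA`), mirroring the source tables.

Simulation-based tests are scaled to run in minutes: parameter-recovery
uses 20 rich IV profiles and 60 sparse field profiles per seed over 3 seeds
(the estimates of `Cl` and `F` then sit well within the +/-20% band the
checks assert); the covariate search power case uses 60 rich profiles over
2 seeds and the null calibration 16 profiles over 3 seeds.  These sizes are
the package's choice of a fast, reproducible experiment; the full-size
synthetic meta-analysis (380 profiles) remains a single
`generate_trials()` call away.

## Known limitations

Linear kinetics only (no saturable absorption or elimination, no lag
times, no zero-order input); diagonal omega; no inter-occasion
variability; BLQ data are discarded rather than modelled; bootstrap is the
only source of parameter uncertainty; and the PK/PD cutoff inherits every
assumption of the final model — in particular the unexplained, very large
between-subject variability of in-feed bioavailability under field
conditions, which is the binding constraint on the cutoffs.
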