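---
title: "Hybrid boosted-Cox risk modelling with coxstack: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid boosted-Cox risk modelling with coxstack: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Primary-prevention cardiovascular risk scores estimate a person's absolute
probability of a first cardiovascular event (coronary heart disease,
stroke, peripheral artery disease, revascularization) over a 10-year
horizon, from routinely collected electronic health records: demographics,
laboratory tests, disease and medication history, family history and
healthcare utilization. Classical scores use a Cox proportional hazards
model over a handful of predictors; EHR data offer a hundred or more
covariates with nonlinear effects (electrolyte levels show U-shaped
associations with cardiovascular hazard) and interactions that a linear
model cannot absorb.

`coxstack` implements a hybrid of the two traditions:

1. **Boosted stage.** A gradient-boosted tree ensemble is trained on all
   eligible covariates against the Cox partial-likelihood objective. For
   a subject with linear predictor $f_j$, follow-up $t_j$ and event
   indicator $\delta_j$, the negative log partial likelihood with Breslow
   handling of ties has per-subject gradient
   $$g_j = e^{f_j}\sum_{i:\ \delta_i=1,\ t_i \le t_j}
        \frac{d_i}{\sum_{k \in R(t_i)} e^{f_k}} - \delta_j,$$
   and the matching diagonal Hessian
   $h_j = e^{f_j}\sum_i d_i/S_0(t_i) - e^{2 f_j}\sum_i d_i/S_0(t_i)^2$,
   where $R(t)$ is the risk set and $d_i$ the event count at $t_i$.
   These derivatives (`cox_objective()`) drive xgboost as a custom
   objective; the ensemble's margin, centred to its training mean, is the
   *boosted risk score* in log-relative-hazard units. The objective is
   pluggable (`loss_hook`), so alternative survival losses can be swapped
   in without touching the boosting machinery.

2. **Stacking stage.** A ridge-penalized Cox model (`ridge_cox()`,
   Newton–Raphson on the Breslow partial likelihood with an L2 penalty on
   standardized coefficients) regresses the hazard on a small set of
   *mandatory* clinical predictors — age, sex, HDL cholesterol, and
   history of dyslipidemia, diabetes, atrial fibrillation, hypertension
   and chronic kidney disease — plus, in the **full** flavor, the boosted
   score as one extra covariate. The **basic** flavor omits the score and
   serves settings where only the mandatory fields are available. The
   Breslow baseline cumulative hazard at the centred linear predictor
   turns the fit into absolute risk:
   $\hat r(x) = 1 - S_0(h)^{\exp(\mathrm{lp}(x) - \bar{\mathrm{lp}})}$.

The ridge penalty stabilizes the coefficients so hazard ratios remain
reportable; the boosted score carries the nonlinear and interaction
structure. By default the score entering the stacking fit is **out-of-fold**
(5-fold cross-fitting, `oof_boosted_scores()`) so its stacking coefficient
is not inflated by in-sample optimism; an in-sample switch exists
(`score =` argument of `fit_stacked()`).

## Cohort assembly

`build_cohort()` turns a long-format record stream into an analysis
cohort: entry at the first entry-marker record (typically the first lipid
test), follow-up to the earliest of first outcome, death, or the study end
date, and the event indicator set when the outcome is earliest. Subjects
are excluded — and tallied in a ledger — when the outcome precedes entry,
when death falls on or before entry, when entry and outcome share a day
(zero follow-up breaks the survival machinery), when any record matches an
exclusion codelist (e.g. congestive heart failure, nitrates, cardiac
glycosides), or when no entry marker exists. Outcome components tied on
the same day are attributed by a configurable priority order, defaulting
to the codelist order, because registry data give no principled tie rule.
Time is internal days; reported years are days/365.25. Entry rules
(marker, minimum age) are configuration, not code, so derivation-style
(lipid test, 18+) and validation-style (blood-pressure record, 35+)
cohorts use the same machinery.

## Preprocessing

* **Eligibility screening** (`screen_variables()`): numeric variables need
  a missing rate below 10%, binary flags a prevalence above 1%; mandatory
  fields always pass. Both thresholds are arguments, and screening is
  monotone in them.
* **Chained-equation imputation** (`mice_impute()`): each incomplete
  numeric variable is regressed on all other eligible variables, with
  Bayesian parameter draws and predictive mean matching (donor pool 5),
  for 10 iterations and m = 5 completed datasets by default. Binary flags
  are treated as complete predictors (absent-equals-zero, the usual EHR
  history semantics) and never imputed. Observed cells are never altered.
  The defaults (m, iterations, donors) follow common chained-equations
  practice and are configuration-exposed. Downstream models fit on the
  first completed dataset by default: a boosted ensemble has no
  Rubin's-rules analogue, so averaging coefficient estimates across
  completions is offered for the linear stage only.
* **Prediction-time imputation** (`mean_impute()`): at scoring time,
  missing mandatory-imputable labs are filled with derivation-cohort
  population means stored in the model, never re-estimated on the target.
* **LASSO shortlisting** (`lasso_screen()`): an L1-penalized Cox path
  (glmnet), penalty chosen by 5-fold cross-validated partial likelihood;
  the nonzero-coefficient variables are refit unpenalized, and variables
  with refit p < 0.05, plus all mandatory ones, form the shortlist. An L1
  fit has no native p-values, so select-then-refit is the only coherent
  reading of "statistically significant LASSO-selected" variables; the
  refit is multivariable on the selected set. Candidates are canonically
  ordered internally so the selected set cannot depend on input order.

## The synthetic cohort generator

Real territory-wide EHR data cannot be shipped, so every stage is
exercised on synthetic cohorts with known ground truth
(`simulate_cohort()`), and the generator is itself tested, first-class
code. The default spec (`default_sim_params()`) emulates a contemporary
EHR-derived primary-prevention population:

* 103 covariates in six clinical groups: 8 mandatory predictors, 8
  additional mean-imputable clinical fields (LDL, HbA1c, systolic and
  diastolic blood pressure, and lipid-modifying / antihypertensive /
  antidiabetic / antiplatelet exposure), ~20 further labs and ~65
  history/medication/family/utilization flags with prevalences from 0.5%
  to 65%.
* Marginals: 55% female; age ~N(58, 14) truncated to 18–100 (median 58,
  matching a median near 57 with IQR 47–67 in the reference population);
  HDL lognormal with median 1.3 and IQR 1.1–1.6 mmol/L.
* Correlation: labs are drawn through a Gaussian copula in physiological
  blocks (lipids, blood pressure, renal, electrolytes, inflammation,
  liver enzymes), so chained-equation imputation has genuinely
  recoverable structure. HDL is deliberately drawn independently of the
  effect-bearing lipid labs: a correlated omitted effect would bias the
  mandatory-only fit and make parameter-recovery testing unreadable.
* True effects: mandatory log hazard ratios fixed at the package's
  reference values (HR 1.04/y age, 0.62 female, 0.70 per mmol/L HDL, 1.89
  dyslipidemia, 1.60 atrial fibrillation, 1.19 hypertension, 1.29
  diabetes, 2.04 chronic kidney disease); moderate linear effects on the
  mean-imputable fields and a few supplementary variables (smoking,
  eGFR, INR); two U-shaped electrolyte effects, parameterized as
  curvature·(x − center)² on sodium (center 140) and potassium (center
  4.4); and two pairwise interactions
  (smoking × family history of premature CVD, NSAID × gout). Supplementary
  effects are independent of the mandatory variables by design, so the
  basic model is approximately well specified for them; what remains is a
  few percent of non-collapsibility attenuation, quantified in the tests.
* Event times by inverse transform from the proportional-hazards Weibull
  model S(t|x) = exp(−(t/scale)^shape·e^lp), shape 1.15, scale calibrated
  once (9000 y; the raw-scale covariate effects give the linear predictor
  a mean near 5.9 that the scale absorbs) so that the observed event
  fraction is ≈ 12.9% — inside the 9–14% band of the reference cohorts.
  Censoring is an exponential dropout (rate ln2/9 per year, non-informative)
  plus a 10-year administrative horizon, giving a median follow-up of
  ≈ 7.1 years.
* Missingness applied post hoc: mandatory labs ≤ 8% (MCAR or MAR with
  logistic dependence on a fully observed variable such as age),
  plus two high-missingness inflammatory markers (CRP 60%, neutrophils
  55%) mirroring how real cohorts lose inflammatory biomarkers.
* Dyslipidemia, atrial fibrillation and chronic kidney disease prevalences
  (15%/6%/6%) sit at the upper end of what EHR problem lists show in a
  late-middle-aged hospital-contact population. The choice is deliberate:
  recovering a log hazard ratio for a 1%-prevalence flag at n = 20,000 is
  statistically hopeless (its standard error alone exceeds a 10% relative
  band), and the generator's purpose is to make parameter recovery a
  meaningful test rather than a lottery. Even so, at n = 20,000 the
  rare-flag coefficients carry standard errors near 0.07, so single-seed
  recovery within ±10% on the hazard-ratio scale retains a noticeable
  failure probability by noise alone; the test suite therefore pairs the
  fixed-seed check with a seed-averaged large-n check of approximate
  unbiasedness.

What the generator does **not** emulate: correlation between disease
flags and their associated labs or treatments (hypertension is independent
of measured blood pressure), informative censoring (available as a switch
in principle but off by default), time-varying effects, calendar drift,
and code-level ICD structure (the long-format path is exercised by small
hand-built streams instead). Passing tests therefore demonstrate the
statistical machinery is correct under proportional hazards with known
truth — not that real EHR confounding is handled.

## Validation suite

All of the model-validation machinery mirrors standard risk-model
practice:

* **Harrell's C** via `survival::concordance` (risk ties count ½; a pair
  is usable iff the shorter time is an event), checked in the tests
  against an O(n²) pair-enumeration oracle.
* **Decile calibration**: subjects ranked by predicted risk into ten
  equal-count groups (identical predictions stay together even if counts
  become unequal — splitting ties would make groups order-dependent);
  mean predicted risk per group against 1 − KM(h). The **calibration
  slope** is the OLS slope of observed on predicted over the groups;
  **calibration-in-the-large** is overall KM risk minus mean predicted
  risk, on the risk scale (some literatures use a logistic intercept; the
  risk-scale difference is the choice here and is reported as such).
* **Brier score** at the horizon with inverse-probability-of-censoring
  weights (Graf construction); with no censoring it reduces exactly to
  the mean squared error.
* **Decision curves**: net benefit TP/n − FP/n·p_t/(1−p_t) on a threshold
  grid of 0.01–0.50 (step 0.01), the clinically relevant range for
  10-year primary prevention; TP/FP among flagged subjects are estimated
  with the Kaplan–Meier event rate inside the flagged group, so censored
  subjects do not bias the curve. Treat-all and treat-none references are
  included.
* **Bootstrap** (`bootstrap_metric()`): subject-level resampling with a
  percentile interval (B = 1000 by default, reduced in tests); percentile
  rather than BCa, as the quantities are smooth functionals at large n.
* **Repeated cross-validation** (`repeated_cv()`): event-stratified
  k-fold, reshuffled each repeat (default 100 × 10-fold).
* **Recalibration** (`recalibrate()`): an intercept shift on the
  log-cumulative-hazard scale (solved so the expected event count matches
  under the model's own baseline shape) and a slope multiplier on the
  centred linear predictor (unpenalized Cox on the score). The update is
  accepted only if neither |slope − 1| nor |CITL| worsens — an
  operationalization of "recalibrate if it improves the calibration
  curve" that replaces a visual judgement with two monotone criteria.

## Numerical choices and edge cases

* Ties: Breslow everywhere (objective, ridge fit, baseline) — the one
  convention consistent with the boosting gradient.
* `ridge_cox` uses Newton–Raphson with step halving; a constant column's
  scale is pinned to 1 so the penalty drives its coefficient to zero
  (this also makes a constant boosted score collapse the full model onto
  the basic one exactly). Wald intervals come from the penalized
  information matrix and are flagged approximate: the penalty biases the
  curvature, and no resampling correction is applied.
* The ridge penalty default is chosen by 5-fold cross-validated partial
  likelihood over a log-spaced grid (the penalty acts on standardized
  coefficients); a numeric `lambda` bypasses the CV.
* Boosted-stage hyperparameter grid: depth {2,3,4} × learning rate
  {0.05, 0.1} × rounds {100, 300} × subsample 0.8, selected by mean
  out-of-fold C with ties broken toward fewer rounds, then shallower
  trees. `rounds = 0` yields a valid constant-score model.
* KM evaluation is right-continuous, carries the last value beyond the
  final observed time, and returns 1 at t = 0; the IPCW Brier errors out
  if the censoring KM hits zero before the horizon.
* Attributions use exact tree-ensemble Shapley values (TreeSHAP via
  xgboost). xgboost accumulates them in single precision, so the
  additivity identity holds to ~1e-6 for moderate ensembles and ~1e-5
  for the 103-variable full model; tolerances in the tests reflect that.
* Problem sizes in the test and acceptance runs — derivation cohorts of
  n = 20,000 with validation draws of 20,000–50,000, B of 30–200 for
  bootstrap intervals, 5 repeats of 10-fold CV — were chosen as the
  smallest sizes at which the checked quantities are stable to well
  within their tolerances.

## Known limitations

* The hazard-ratio intervals from a penalized information matrix are
  approximate; for strict inference refit the selected model unpenalized.
* No multiple-imputation variance pooling for the boosted stage.
* The simulator's independence between flags and labs means confounding
  structures seen in real EHR data are untested here.
* Published comparator scores (pooled cohort equations and similar) are
  not re-implemented; an external score enters `compare_models()` as a
  plain risk column.
* Time-varying covariate effects are out of scope.
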