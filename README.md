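# coxstack

Hybrid boosted + penalized Cox modelling for 10-year cardiovascular risk
prediction on EHR-style cohorts.

Classical primary-prevention risk scores are Cox proportional hazards
models over a handful of predictors; electronic health records offer a
hundred or more covariates with nonlinear (e.g. U-shaped electrolyte) and
interaction effects. `coxstack` implements a hybrid: a gradient-boosted
tree ensemble is trained with the Cox partial-likelihood objective

    grad_j = exp(f_j) * sum_{i: d_i=1, t_i <= t_j} d_i / S0(t_i)  -  delta_j,
    S0(t)  = sum_{k in R(t)} exp(f_k)            (Breslow ties),

and its centred out-of-fold score is stacked as a single covariate into a
ridge-penalized Cox model over eight mandatory clinical predictors (age,
sex, HDL cholesterol, dyslipidemia, diabetes, atrial fibrillation,
hypertension, chronic kidney disease). The Breslow baseline turns the fit
into absolute risk, `risk = 1 - S0(h)^exp(lp - center)`. A **basic**
flavor (mandatory variables only) serves low-information settings; the
**full** flavor adds the boosted score.

Around the core model the package provides the working parts of a risk
modelling study: cohort assembly from longitudinal records (entry at
first lipid test, censoring at first event/death/study end, exclusion
ledger), eligibility screening (<10% missing, >1% prevalence),
chained-equation imputation with predictive mean matching, population-mean
imputation at prediction time, LASSO shortlisting, and a validation suite
(Harrell's C with bootstrap intervals, decile calibration against
Kaplan–Meier, calibration slope, calibration-in-the-large, IPCW Brier
score, decision curves, repeated cross-validation, recalibration). A
synthetic cohort generator with known ground truth makes everything
testable without patient data.

## Worked example

```r
library(coxstack)

params <- default_sim_params(n = 20000, seed = 1)   # ~103 covariates
sim    <- simulate_cohort(params, seed = 1)

basic <- derive_model(sim$cohort, "basic", seed = 1)
full  <- derive_model(sim$cohort, "full",  seed = 1)
print(full)

val <- simulate_cohort(params, seed = 2)            # independent draw
compare_models(list(basic = basic, full = full), val$cohort, B = 50, seed = 1)
```

On the default synthetic cohort this prints (values from an actual run):

```
#>   model     c c_lower c_upper slope      citl brier
#> 1 basic 0.677   0.669   0.686 0.930  0.000216 0.107
#> 2  full 0.717   0.707   0.725 0.992 -0.000147 0.101
```

The full model's bootstrap validation C of 0.717 against 0.677 for the basic model
(a gap of 0.04) reflects the supplementary, nonlinear and interaction
signal that only the boosted score can reach; the full model's
calibration slope of 0.99 and calibration-in-the-large of ~0 say its
absolute 10-year risks are honest on a fresh cohort from the same
population. `hazard_ratios(basic)` prints the fitted mandatory hazard
ratios (e.g. female 0.61, CKD 1.91 at this seed against generator truth
0.62 and 2.04) with approximate Wald intervals.

A command-line interface wraps the same functions
(`inst/cli/coxstack`): `simulate`, `build-cohort`, `preprocess`,
`derive`, `validate`, `report` compose into a reproducible pipeline with
seeds embedded in every JSON artifact.

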