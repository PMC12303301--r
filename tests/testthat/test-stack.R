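test_that("ridge Cox at vanishing penalty matches the unpenalized fit", {
  set.seed(5)
  n <- 600
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tm <- rexp(n, exp(X %*% c(0.5, -0.3, 0.2)))
  ev <- rbinom(n, 1, 0.7)
  f1 <- ridge_cox(X, tm, ev, lambda = 1e-8)
  f2 <- survival::coxph(survival::Surv(tm, ev) ~ X, ties = "breslow")
  expect_equal(unname(f1$coef), unname(coef(f2)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(solve(f1$info)))),
               unname(sqrt(diag(vcov(f2)))), tolerance = 1e-6)
})

test_that("ridge coefficient norms shrink monotonically along the penalty path", {
  set.seed(6)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  tm <- rexp(n, exp(X %*% c(0.6, -0.4, 0.3, 0)))
  ev <- rbinom(n, 1, 0.8)
  norms <- vapply(c(0.1, 1, 10, 100, 1000, 1e5), function(lam) {
    sqrt(sum(ridge_cox(X, tm, ev, lam)$coef_std^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-2)
  expect_error(ridge_cox(X, tm, ev, lambda = -1), "non-negative")
})

test_that("ridge fit agrees with glmnet at a shared penalty", {
  set.seed(7)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tm <- rexp(n, exp(X %*% c(0.5, -0.3, 0)))
  ev <- rbinom(n, 1, 0.7)
  lam <- 5
  f1 <- ridge_cox(X, tm, ev, lambda = lam)
  # glmnet minimizes -(2/n) logPL + lambda_g * ||b||^2 / 2 ... its lambda
  # maps to ours as lambda = n * lambda_g (both on standardized scale)
  f2 <- glmnet::glmnet(X, survival::Surv(tm, ev), family = "cox", alpha = 0,
                       lambda = lam / n, standardize = TRUE, thresh = 1e-12)
  expect_equal(unname(f1$coef), as.vector(coef(f2)), tolerance = 0.02)
})

test_that("a constant boosted score collapses the full model onto the basic one", {
  p <- quick_params(n = 1500, p = 2, beta = c(v01 = 0.5, v02 = -0.3), seed = 3)
  s <- simulate_cohort(p, seed = 3)
  s$cohort$catalog$mandatory <- TRUE
  m0 <- fit_boosted(s$cohort, c("v01", "v02"),
                    boost_hyperparams(rounds = 0), seed = 1)
  basic <- fit_stacked(s$cohort, lambda = 2, flavor = "basic")
  full <- fit_stacked(s$cohort, boosted = m0, lambda = 2, flavor = "full")
  expect_equal(full$coef[c("v01", "v02")], basic$coef, tolerance = 1e-6)
  expect_equal(unname(full$coef["boost_score"]), 0)
})

test_that("absolute risk follows the closed form and its monotonicities", {
  s0 <- data.frame(time = c(5, 10), cumhaz = c(0.05, -log(0.9)),
                   surv = c(exp(-0.05), 0.9))
  model <- structure(list(coef = c(x = 0.5), info = diag(1), lambda = 0,
                          center = 0, s0 = s0, flavor = "basic",
                          boosted = NULL, imputation = NULL,
                          variables = "x", horizon = 10),
                     class = "stacked_model")
  # S0(10) = 0.9, centred lp = 0 -> 0.100 ; lp = ln 2 -> 1 - 0.81 = 0.190
  expect_equal(predict_risk(model, data.frame(x = 0)), 0.1)
  expect_equal(predict_risk(model, data.frame(x = log(2) / 0.5)), 0.19)
  # increasing in a positive-coefficient feature and in the horizon
  r <- predict_risk(model, data.frame(x = seq(-2, 2, length.out = 9)))
  expect_true(all(diff(r) > 0))
  expect_lte(predict_risk(model, data.frame(x = 1), horizon = 5),
             predict_risk(model, data.frame(x = 1), horizon = 10))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(predict_risk(model, data.frame(y = 1)), "missing mandatory")
})

test_that("risk prediction mean-imputes stored lab fields and errors otherwise", {
  p <- default_sim_params(n = 3000, seed = 5)
  s <- simulate_cohort(p, seed = 5)
  m <- derive_model(s$cohort, "basic", lambda = 1, seed = 5)
  one <- s$cohort$data[7, ]
  one$hdl <- NA_real_
  r <- predict_risk(m, one)
  expect_true(r >= 0 && r <= 1)
  one2 <- one[setdiff(names(one), "hdl")]
  expect_error(predict_risk(m, one2), "hdl")
})

test_that("parameter recovery on the well-specified core generator", {
  s <- simulate_cohort(mandatory_only_params(20000), seed = 41)
  m <- fit_stacked(s$cohort, lambda = 1, flavor = "basic")
  truth <- s$truth$beta[names(m$coef)]
  rel_hr_err <- exp(m$coef - truth) - 1
  expect_lt(max(abs(rel_hr_err)), 0.15)
  # approximate unbiasedness: averaging the mandatory-only fit over three
  # independent large draws of the default generator stays within the 10%
  # hazard-ratio band (the residual is non-collapsibility attenuation from
  # the omitted supplementary effects, a few percent)
  coefs <- vapply(c(42, 43, 44), function(sd) {
    sb <- simulate_cohort(default_sim_params(n = 60000), seed = sd)
    Xb <- coxstack:::cohort_matrix(sb$cohort, MANDATORY_8)
    Xb[is.na(Xb[, "hdl"]), "hdl"] <- mean(Xb[, "hdl"], na.rm = TRUE)
    ridge_cox(Xb, sb$cohort$data$followup_years, sb$cohort$data$event,
              lambda = 1)$coef
  }, numeric(8))
  err_b <- exp(rowMeans(coefs) - s$truth$beta[MANDATORY_8]) - 1
  expect_lt(max(abs(err_b)), 0.10)
})

test_that("hazard ratio table is internally consistent", {
  set.seed(8)
  n <- 800
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  tm <- rexp(n, exp(X %*% c(0.4, 0)))
  ev <- rbinom(n, 1, 0.75)
  d <- data.frame(subject_id = as.character(1:n), followup_years = tm,
                  event = ev, a = X[, 1], b = X[, 2])
  cat <- variable_catalog(c("a", "b"), kind = "numeric", mandatory = TRUE,
                          group = "lab")
  m <- fit_stacked(cohort_table(d, cat), lambda = 0.5, flavor = "basic")
  hr <- hazard_ratios(m)
  expect_equal(hr$hr, exp(m$coef), ignore_attr = TRUE)
  expect_true(all(hr$lower < hr$hr & hr$hr < hr$upper))
  # near-zero coefficient: HR ~ 1, CI straddles 1, p large
  expect_gt(hr$p[hr$name == "b"], 0.05)
  expect_lt(hr$lower[hr$name == "b"], 1)
  expect_gt(hr$upper[hr$name == "b"], 1)
  expect_true(isTRUE(attr(hr, "approximate")))
})

test_that("full model's boosted-score coefficient is positive on signal", {
  p <- quick_params(n = 4000, p = 3, beta = c(v01 = 0.6, v02 = -0.4),
                    nonlinear = list(list(type = "interaction", var_a = "v01",
                                          var_b = "v03", weight = 0.5)),
                    scale = 25, seed = 9)
  s <- simulate_cohort(p, seed = 9)
  s$cohort$catalog$mandatory <- c(TRUE, TRUE, FALSE)
  vars <- c("v01", "v02", "v03")
  hp <- boost_hyperparams(rounds = 80)
  b <- fit_boosted(s$cohort, vars, hp, seed = 2)
  sc <- oof_boosted_scores(s$cohort, vars, hp, seed = 2)
  m <- fit_stacked(s$cohort, boosted = b, score = sc, lambda = 1,
                   flavor = "full")
  expect_gt(unname(m$coef["boost_score"]), 0)
})
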