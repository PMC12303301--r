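test_that("concordance matches hand enumeration and the brute-force oracle", {
  # perfectly anti-ordered risks, all events
  expect_equal(harrells_c(c(4, 3, 2, 1), c(1, 2, 3, 4), rep(1, 4)), 1)
  # hand-enumerated 6 pairs: 4 concordant
  expect_equal(harrells_c(c(0.9, 0.1, 0.8, 0.2), c(2, 4, 6, 8), rep(1, 4)),
               4 / 6)
  # oracle equivalence on random censored instances
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    tm <- rexp(n)           # continuous: no tied times
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1
    r <- sample(seq_len(n) %% 7)  # tied risks occur
    expect_equal(harrells_c(r, tm, ev), brute_force_c(r, tm, ev))
  }
})

test_that("concordance is invariant under monotone transforms of risk", {
  set.seed(14)
  tm <- rexp(50); ev <- rbinom(50, 1, 0.5); if (sum(ev) == 0) ev[1] <- 1
  r <- runif(50)
  c0 <- harrells_c(r, tm, ev)
  expect_equal(harrells_c(qlogis(r), tm, ev), c0)
  expect_equal(harrells_c(100 * r + 3, tm, ev), c0)
})

test_that("bootstrap metric is deterministic with degenerate-width constants", {
  p <- quick_params(n = 200, p = 2, seed = 1)
  s <- simulate_cohort(p, seed = 1)
  b1 <- bootstrap_metric(function(ct) 7, s$cohort, B = 50, seed = 2)
  expect_equal(b1$mean, 7)
  expect_equal(b1$upper - b1$lower, 0)
  f <- function(ct) mean(ct$data$followup_years)
  b2 <- bootstrap_metric(f, s$cohort, B = 100, seed = 3)
  b3 <- bootstrap_metric(f, s$cohort, B = 100, seed = 3)
  expect_identical(b2, b3)
  expect_error(bootstrap_metric(f, s$cohort, B = 1), "at least 2")
})

test_that("bootstrap percentile interval attains nominal coverage for a mean", {
  set.seed(15)
  cover <- vapply(1:100, function(k) {
    x <- data.frame(val = rnorm(200))
    ci <- bootstrap_metric(function(d) mean(d$val), x, B = 200, seed = k)
    ci$lower <= 0 && 0 <= ci$upper
  }, TRUE)
  expect_equal(mean(cover), 0.95, tolerance = 0.05)
})

test_that("repeated cross-validation is reproducible and calibrated under the null", {
  p <- quick_params(n = 3000, p = 2, seed = 2)
  s <- simulate_cohort(p, seed = 7)
  fit <- function(tr) survival::coxph(
    survival::Surv(followup_years, event) ~ v01 + v02, data = tr$data)
  score <- function(m, te) predict(m, newdata = te$data)
  cv1 <- repeated_cv(s$cohort, fit, score, k = 10, repeats = 2, seed = 3)
  cv2 <- repeated_cv(s$cohort, fit, score, k = 10, repeats = 2, seed = 3)
  expect_identical(cv1, cv2)
  expect_length(cv1, 2)
  cv <- repeated_cv(s$cohort, fit, score, k = 10, repeats = 5, seed = 3)
  expect_lt(abs(mean(cv) - 0.5), 0.02)
  # fewer events than folds errors
  tiny <- s$cohort
  tiny$data <- tiny$data[order(-tiny$data$event)[1:12], ]
  tiny$data$event[3:12] <- 0
  expect_error(repeated_cv(tiny, fit, score, k = 10, repeats = 1, seed = 1),
               "fewer events")
})

test_that("decile calibration groups by rank, keeps ties together, flags degeneracy", {
  set.seed(16)
  r <- runif(100)
  tm <- rexp(100, 0.05); ev <- rbinom(100, 1, 0.5)
  tab <- decile_calibration(r, tm, ev, horizon = 10)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$n, rep(10, 10))
  # group boundaries match a hand ranking
  expect_equal(tab$mean_predicted,
               vapply(split(sort(r), rep(1:10, each = 10)), mean, 0),
               ignore_attr = TRUE)
  expect_true(all(diff(tab$mean_predicted) > 0))
  # heavy ties: coarser grouping with a warning
  r2 <- rep(c(0.1, 0.9), each = 50)
  expect_warning(tab2 <- decile_calibration(r2, tm, ev, horizon = 10),
                 "coarser")
  expect_equal(nrow(tab2), 2)
  # constant risks: documented error path
  expect_error(decile_calibration(rep(0.3, 100), tm, ev, 10), "degenerate")
})

test_that("calibration slope reproduces hand least-squares results", {
  mk <- function(pred, obs) {
    structure(data.frame(group = seq_along(pred), n = 10,
                         mean_predicted = pred, km_observed = obs,
                         km_lower = obs, km_upper = obs),
              class = c("calibration_table", "data.frame"))
  }
  expect_equal(calibration_slope(mk(1:10 / 20, 1:10 / 20)), 1.0)
  expect_equal(calibration_slope(mk(1:10 / 20, 1:10 / 10)), 2.0)
  # 3-point hand OLS: slope = 0.021 / 0.02 = 1.05
  expect_equal(calibration_slope(mk(c(0.1, 0.2, 0.3), c(0.12, 0.19, 0.33))),
               1.05)
  expect_error(calibration_slope(mk(c(0.2, 0.2), c(0.1, 0.3))), "degenerate")
})

test_that("calibration-in-the-large obeys its closed-form identities", {
  set.seed(17)
  n <- 2000
  tm <- rexp(n, 0.08); ev <- rep(1, n)   # no censoring
  obs <- mean(tm <= 10)
  pred <- rep(0.2, n)
  expect_equal(calibration_in_the_large(pred, tm, ev, 10), obs - 0.2)
  # inflating predictions by +0.05 shifts CITL by -0.05
  base <- runif(n, 0.05, 0.4)
  expect_equal(calibration_in_the_large(base + 0.05, tm, ev, 10),
               calibration_in_the_large(base, tm, ev, 10) - 0.05)
})

test_that("Brier score reduces to MSE without censoring and matches hand IPCW", {
  # perfect 0/1 predictions, no censoring
  tm <- c(1, 2, 20, 30); ev <- rep(1, 4)
  expect_equal(brier_score(c(1, 1, 0, 0), tm, ev, 10), 0)
  expect_equal(brier_score(rep(0.5, 4), tm, ev, 10), 0.25)
  set.seed(18)
  n <- 300
  tm2 <- rexp(n, 0.1); ev2 <- rep(1, n)
  r2 <- runif(n)
  y <- as.numeric(tm2 <= 10)
  expect_equal(brier_score(r2, tm2, ev2, 10), mean((y - r2)^2))
  # hand IPCW: events weighted by 1/G(T-), survivors by 1/G(h)
  # subjects: event@2 (r=.8), censored@3 (r=.5), event@6>h? no: horizon 5
  tm3 <- c(2, 3, 6, 7); ev3 <- c(1, 0, 1, 0); r3 <- c(0.8, 0.5, 0.4, 0.1)
  # censoring KM: drop at t=3 with 3 at risk -> G = 2/3 on [3, 7)
  hand <- ((1 - 0.8)^2 / 1 + 0 + 0.4^2 / (2/3) + 0.1^2 / (2/3)) / 4
  expect_equal(brier_score(r3, tm3, ev3, 5), hand)
})

test_that("decision curve matches the hand example and its limits", {
  # 10 subjects, 4 events, 5 flagged of whom 3 are true positives
  r <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1, 0.1, 0.1, 0.1, 0.1)
  tm <- c(1, 2, 3, 20, 30, 40, 50, 60, 70, 5)
  ev <- rep(1, 10)   # no censoring; events before horizon 10: subjects 1,2,3,10
  dc <- decision_curve(r, tm, ev, horizon = 10, thresholds = c(0.2))
  expect_equal(dc$nb_model, 0.3 - 0.2 * 0.25)
  expect_equal(dc$nb_none, 0)
  # treat-all at the same threshold
  expect_equal(dc$nb_all, 0.4 - 0.6 * 0.25)
  # threshold -> 0: model (all flagged) and treat-all tend to prevalence
  dc0 <- decision_curve(r + 0.05, tm, ev, horizon = 10, thresholds = 1e-6)
  expect_equal(dc0$nb_model, 0.4, tolerance = 1e-4)
  expect_equal(dc0$nb_all, 0.4, tolerance = 1e-4)
  # treat-none is identically zero across the default grid
  dcg <- decision_curve(r, tm, ev, horizon = 10)
  expect_true(all(dcg$nb_none == 0))
  expect_true(all(dcg$threshold < 1))
})

test_that("recalibration recovers a doubled baseline hazard and obeys its acceptance rule", {
  m <- fit_stacked(simulate_cohort(mandatory_only_params(8000), seed = 31)$cohort,
                   lambda = 1, flavor = "basic")
  pt <- mandatory_only_params(15000)
  pt$baseline$scale <- 256 * 2^(-1 / pt$baseline$shape)  # doubles H0(t)
  tg <- simulate_cohort(pt, seed = 33)
  rc <- recalibrate(m, tg$cohort, 10)
  expect_equal(rc$shift, log(2), tolerance = 0.1 * log(2))
  expect_lt(abs(rc$after$citl), abs(rc$before$citl))
  expect_true(rc$accepted)
  # self-target: update is rejected or is a near-identity
  self <- simulate_cohort(mandatory_only_params(15000), seed = 34)
  rc2 <- recalibrate(m, self$cohort, 10)
  expect_true(!rc2$accepted ||
                (abs(rc2$slope_mult - 1) <= 0.06 && abs(rc2$shift) <= 0.06))
  expect_error(recalibrate(m, {
    z <- self$cohort; z$data$event <- 0; z
  }, 10), "no events")
})

test_that("model comparison table is consistent with individual reports", {
  s <- simulate_cohort(mandatory_only_params(4000), seed = 35)
  m <- fit_stacked(s$cohort, lambda = 1, flavor = "basic")
  v <- simulate_cohort(mandatory_only_params(4000), seed = 36)
  tab <- compare_models(list(basic = m), v$cohort, B = 30, seed = 4)
  rep1 <- validate_model(m, v$cohort, B = 30, seed = 4)
  expect_equal(tab$c, rep1$c_mean)
  expect_equal(tab$brier, rep1$brier)
  tab2 <- compare_models(list(basic = m), v$cohort, B = 30, seed = 4)
  expect_equal(tab, tab2, ignore_attr = TRUE)
})
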