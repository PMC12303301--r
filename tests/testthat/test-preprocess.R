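make_screen_cohort <- function() {
  n <- 1000
  set.seed(1)
  d <- data.frame(
    subject_id = sprintf("s%04d", 1:n),
    followup_years = rexp(n, 0.2) + 0.01,
    event = rbinom(n, 1, 0.2),
    lab_ok = rnorm(n), lab_bad = rnorm(n), hdl = rnorm(n, 1.3, 0.3),
    flag_rare = rbinom(n, 1, 0.005), flag_common = rbinom(n, 1, 0.3)
  )
  d$lab_bad[1:120] <- NA     # 12% missing
  d$lab_ok[1:50] <- NA       # 5% missing
  d$hdl[1:150] <- NA         # 15% missing but mandatory
  cat <- variable_catalog(
    c("lab_ok", "lab_bad", "hdl", "flag_rare", "flag_common"),
    kind = c("numeric", "numeric", "numeric", "binary", "binary"),
    group = c("lab", "lab", "lab", "disease_history", "disease_history"),
    mandatory = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  cohort_table(d, cat)
}

test_that("screening applies the 10% missing and 1% prevalence rules", {
  ct <- make_screen_cohort()
  rep <- screen_variables(ct)
  get <- function(v, col) rep[[col]][rep$name == v]
  expect_true(get("lab_ok", "eligible"))        # 5% missing
  expect_false(get("lab_bad", "eligible"))      # 12% missing
  expect_false(get("flag_rare", "eligible"))    # 0.5% prevalence
  expect_true(get("flag_common", "eligible"))   # 30% prevalence
  expect_true(get("hdl", "eligible"))           # mandatory override
  expect_match(get("hdl", "reason"), "mandatory override")
  # a flag just above the threshold is eligible
  rep2 <- screen_variables(ct, event_threshold = 0.001)
  expect_true(rep2$eligible[rep2$name == "flag_rare"])
})

test_that("screening is monotone in its thresholds", {
  ct <- make_screen_cohort()
  strict <- eligible_vars(screen_variables(ct, missing_threshold = 0.03,
                                           event_threshold = 0.05))
  loose <- eligible_vars(screen_variables(ct, missing_threshold = 0.20,
                                          event_threshold = 0.001))
  expect_true(all(strict %in% loose))
})

test_that("chained-equation imputation is deterministic and leaves observed cells intact", {
  p <- quick_params(n = 400, p = 3, beta = c(v01 = 0.4),
                    missingness = list(v02 = list(rate = 0.25, mechanism = "MCAR")))
  s <- simulate_cohort(p, seed = 11)
  i1 <- mice_impute(s$cohort, m = 2, iterations = 3, seed = 5,
                    vars = c("v01", "v02", "v03"))
  i2 <- mice_impute(s$cohort, m = 2, iterations = 3, seed = 5,
                    vars = c("v01", "v02", "v03"))
  expect_identical(i1$completed[[1]]$data, i2$completed[[1]]$data)
  obs <- !is.na(s$cohort$data$v02)
  for (k in 1:2) {
    expect_identical(i1$completed[[k]]$data$v02[obs], s$cohort$data$v02[obs])
    expect_false(anyNA(i1$completed[[k]]$data$v02))
  }
  # no missingness: identity for all m
  p0 <- quick_params(n = 100, p = 2)
  s0 <- simulate_cohort(p0, seed = 1)
  i0 <- mice_impute(s0$cohort, m = 3, seed = 2, vars = c("v01", "v02"))
  for (k in 1:3) expect_identical(i0$completed[[k]]$data, s0$cohort$data)
  # 100% missing is an error
  sbad <- s0
  sbad$cohort$data$v01 <- NA_real_
  expect_error(mice_impute(sbad$cohort, vars = c("v01", "v02")), "100%")
})

test_that("chained-equation imputation beats mean imputation under MAR", {
  covs <- list(
    list(name = "x1", kind = "numeric", group = "lab",
         dist = list(type = "normal", mean = 0, sd = 1), block = "b", rho = 0.8),
    list(name = "x2", kind = "numeric", group = "lab",
         dist = list(type = "normal", mean = 0, sd = 1), block = "b", rho = 0.8))
  p <- sim_params(n = 2000, covariates = covs, beta = c(x1 = 0.3),
                  baseline = list(shape = 1, scale = 50),
                  censoring = list(horizon = 10, dropout_rate = 0),
                  missingness = list(x2 = list(rate = 0.3,
                                               mechanism = list(type = "MAR", on = "x1"))),
                  seed = 9)
  s <- simulate_cohort(p, seed = 9)
  p_true <- p; p_true$missingness <- list()
  truth <- simulate_cohort(p_true, seed = 9)$cohort$data$x2  # masking is post hoc
  d <- s$cohort$data
  idx <- is.na(d$x2)
  imp <- mice_impute(s$cohort, m = 5, iterations = 5, seed = 3,
                     vars = c("x1", "x2"))
  est <- rowMeans(vapply(imp$completed, function(ct) ct$data$x2,
                         numeric(nrow(d))))
  rmse_mice <- sqrt(mean((est[idx] - truth[idx])^2))
  rmse_mean <- sqrt(mean((mean(d$x2, na.rm = TRUE) - truth[idx])^2))
  expect_lt(rmse_mice, rmse_mean)
})

test_that("population-mean imputation fills only missing numeric fields", {
  p <- quick_params(n = 300, p = 2,
                    missingness = list(v01 = list(rate = 0.2, mechanism = "MCAR")))
  s <- simulate_cohort(p, seed = 3)
  imp <- mice_impute(s$cohort, m = 1, seed = 1, vars = c("v01", "v02"))
  mdl <- imp$model
  expect_equal(unname(mdl$population_means["v01"]),
               mean(s$cohort$data$v01, na.rm = TRUE))
  full <- mean_impute(list(v01 = 1.5, v02 = -0.2), mdl)
  expect_equal(full, list(v01 = 1.5, v02 = -0.2))
  part <- mean_impute(list(v01 = NA, v02 = -0.2), mdl)
  expect_equal(part$v01, unname(mdl$population_means["v01"]))
  allmiss <- mean_impute(list(v01 = NA, v02 = NA, flag = 1), mdl)
  expect_equal(allmiss$v01, unname(mdl$population_means["v01"]))
  expect_equal(allmiss$v02, unname(mdl$population_means["v02"]))
  expect_equal(allmiss$flag, 1)  # binary flags untouched
})

test_that("lasso screening finds true support and forces mandatory variables", {
  covs <- lapply(sprintf("v%02d", 1:50), function(nm) {
    list(name = nm, kind = "numeric", group = "lab",
         dist = list(type = "normal", mean = 0, sd = 1))
  })
  beta <- c(v01 = 0.4, v02 = -0.35, v03 = 0.3, v04 = 0.5, v05 = -0.45)
  p <- sim_params(n = 10000, covariates = covs, beta = beta,
                  baseline = list(shape = 1, scale = 30),
                  censoring = list(horizon = 10, dropout_rate = 0.05), seed = 6)
  s <- simulate_cohort(p, seed = 6)
  sel <- lasso_screen(s$cohort, seed = 6)
  expect_true(all(names(beta) %in% sel$selected))
  # invariance to candidate ordering at fixed seed
  sel3 <- lasso_screen(s$cohort, candidates = rev(sprintf("v%02d", 1:50)),
                       seed = 6)
  expect_setequal(sel3$selected, sel$selected)
  # mandatory variable with zero true effect is still selected
  s$cohort$catalog$mandatory[s$cohort$catalog$name == "v50"] <- TRUE
  sel2 <- lasso_screen(s$cohort, seed = 6)
  expect_true("v50" %in% sel2$selected)
})

test_that("lasso screening controls false selections under the null", {
  covs <- lapply(sprintf("v%02d", 1:50), function(nm) {
    list(name = nm, kind = "numeric", group = "lab",
         dist = list(type = "normal", mean = 0, sd = 1))
  })
  p0 <- sim_params(n = 1500, covariates = covs,
                   baseline = list(shape = 1, scale = 20),
                   censoring = list(horizon = 10, dropout_rate = 0.05), seed = 1)
  fs <- vapply(1:20, function(k) {
    s0 <- simulate_cohort(p0, seed = 100 + k)
    length(suppressWarnings(lasso_screen(s0$cohort, seed = k))$selected)
  }, 0)
  expect_lte(mean(fs), 0.05 * 50)
})
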