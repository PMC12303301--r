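# Ridge-penalized Cox partial likelihood via Newton-Raphson with Breslow
# ties. Authored in-package: the stacking stage needs the penalized
# information matrix (Wald intervals) and the Breslow baseline, which the
# generic penalized-regression packages do not expose.

# event-time aggregates for score/Hessian; X already standardized
cox_pl_parts <- function(X, times, events, beta) {
  ord <- order(times, decreasing = TRUE)
  Xo <- X[ord, , drop = FALSE]
  lp <- as.vector(Xo %*% beta)
  w <- exp(lp)
  e_s <- events[ord]
  grp <- match(times[ord], unique(times[ord]))
  last_idx <- cumsum(tabulate(grp))
  p <- ncol(X)
  cum0 <- cumsum(w)
  S0_u <- cum0[last_idx]
  d_u <- as.vector(rowsum(e_s, grp))
  ev_u <- d_u > 0
  lp_sum_u <- as.vector(rowsum(lp * e_s, grp))
  negpl <- -sum(lp_sum_u[ev_u] - d_u[ev_u] * log(S0_u[ev_u]))

  WX <- Xo * w
  S1_u <- apply(WX, 2, cumsum)[last_idx, , drop = FALSE]
  xev <- colSums(Xo[e_s == 1, , drop = FALSE])
  M <- S1_u[ev_u, , drop = FALSE] / S0_u[ev_u]
  dv <- d_u[ev_u]
  U <- xev - colSums(M * dv)

  # pairwise second-moment cumulative sums
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  S2p <- matrix(0, sum(ev_u), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    S2p[, k] <- cumsum(WX[, i] * Xo[, j])[last_idx][ev_u]
  }
  a <- colSums(S2p * (dv / S0_u[ev_u]))
  A <- matrix(0, p, p)
  A[pairs] <- a
  A[pairs[, c(2, 1), drop = FALSE]] <- a
  H <- A - crossprod(M * sqrt(dv))
  list(negpl = negpl, U = U, H = H)
}

#' Ridge-penalized Cox proportional hazards fit
#'
#' Maximizes the Breslow partial likelihood minus an L2 penalty
#' `lambda/2 * sum(beta_std^2)` (penalty on the standardized scale) by
#' Newton-Raphson with step halving. Returns coefficients on the original
#' scale together with the penalized information matrix, from which
#' approximate Wald intervals are derived.
#'
#' @param X numeric covariate matrix (complete).
#' @param times,events follow-up times and 0/1 indicators.
#' @param lambda ridge penalty (>= 0).
#' @param max_iter,tol Newton controls.
#' @return list: `coef` (original scale), `coef_std`, `info` (penalized
#'   Hessian, original scale), `negpl`, `lambda`, `center`, `scale`.
#' @export
ridge_cox <- function(X, times, events, lambda = 1, max_iter = 50,
                      tol = 1e-9) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (sum(events) == 0) stop("no events")
  if (anyNA(X)) stop("covariates contain missing values; impute first")
  p <- ncol(X)
  xbar <- colMeans(X)
  xsd <- apply(X, 2, stats::sd)
  xsd[xsd < 1e-12] <- 1   # constant column: coefficient pinned near 0 by penalty
  Xs <- sweep(sweep(X, 2, xbar), 2, xsd, "/")
  beta <- rep(0, p)
  parts <- cox_pl_parts(Xs, times, events, beta)
  f <- parts$negpl + lambda / 2 * sum(beta^2)
  for (it in seq_len(max_iter)) {
    g <- -parts$U + lambda * beta
    Hp <- parts$H + diag(lambda, p)
    delta <- solve(Hp, g)
    step <- 1
    repeat {
      beta_new <- beta - step * delta
      parts_new <- cox_pl_parts(Xs, times, events, beta_new)
      f_new <- parts_new$negpl + lambda / 2 * sum(beta_new^2)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      step <- step / 2
      if (step < 1e-8) break
    }
    conv <- abs(f - f_new) < tol * (abs(f) + 1)
    beta <- beta_new; parts <- parts_new; f <- f_new
    if (conv) break
  }
  coef_orig <- beta / xsd
  names(coef_orig) <- colnames(X)
  D <- diag(xsd, p)
  info_orig <- D %*% (parts$H + diag(lambda, p)) %*% D
  dimnames(info_orig) <- list(colnames(X), colnames(X))
  list(coef = coef_orig, coef_std = beta, info = info_orig,
       negpl = parts$negpl, lambda = lambda, center = xbar, scale = xsd)
}

# 5-fold cross-validated partial likelihood over a log-spaced lambda grid
cv_ridge_lambda <- function(X, times, events, lambdas = 10^seq(-2, 3, length.out = 6),
                            folds = 5, seed = 1L) {
  set.seed(as.integer(seed))
  fid <- sample(rep_len(seq_len(folds), nrow(X)))
  cvloss <- vapply(lambdas, function(lam) {
    loss <- 0
    for (f in seq_len(folds)) {
      tr <- fid != f
      fit <- ridge_cox(X[tr, , drop = FALSE], times[tr], events[tr], lam)
      te <- !tr
      if (sum(events[te]) == 0) next
      lp_te <- as.vector(X[te, , drop = FALSE] %*% fit$coef)
      loss <- loss + neg_log_partial_lik(lp_te, times[te], events[te])
    }
    loss
  }, 0)
  lambdas[which.min(cvloss)]
}

breslow_baseline <- function(lp, times, events, center, horizon = NULL) {
  ord <- order(times)
  t_o <- times[ord]; e_o <- events[ord]
  w <- exp(lp[ord] - center)
  rev_cum <- rev(cumsum(rev(w)))           # sum over {k : t_k >= t_i} (ascending)
  grp <- match(t_o, unique(t_o))
  first_idx <- which(!duplicated(grp))
  S0_u <- rev_cum[first_idx]
  d_u <- as.vector(rowsum(e_o, grp))
  keep <- d_u > 0
  t_u <- unique(t_o)[keep]
  H0 <- cumsum(d_u[keep] / S0_u[keep])
  grid_t <- t_u; grid_H <- H0
  if (!is.null(horizon) && (length(grid_t) == 0 || max(grid_t) < horizon)) {
    grid_t <- c(grid_t, horizon)
    grid_H <- c(grid_H, if (length(grid_H)) grid_H[length(grid_H)] else 0)
  }
  data.frame(time = grid_t, cumhaz = grid_H, surv = exp(-grid_H))
}

baseline_surv_at <- function(s0, t) {
  i <- findInterval(t, s0$time)
  ifelse(i == 0L, 1, s0$surv[pmax(i, 1L)])
}

#' Fit the stacked risk model
#'
#' The core of the hybrid method: a ridge-penalized Cox proportional
#' hazards model over the mandatory risk variables, optionally augmented
#' with the boosted risk score as one additional covariate (`flavor =
#' "full"`). The Breslow baseline survival at the centred linear predictor
#' is stored on a time grid including the prediction horizon, so the model
#' yields absolute risks.
#'
#' @param cohort a complete `cohort_table` (post-imputation).
#' @param mandatory optional mandatory variable names; default from the
#'   catalog.
#' @param boosted a `boosted_cox_model` (required for `flavor = "full"`).
#' @param score optional per-subject boosted score used for the stacking
#'   column (e.g. out-of-fold scores from [oof_boosted_scores()]); default
#'   = in-sample scores from `boosted`.
#' @param lambda ridge penalty; `NULL` selects it by 5-fold cross-validated
#'   partial likelihood over a log grid.
#' @param flavor `"basic"` (mandatory variables only) or `"full"`.
#' @param horizon prediction horizon in years kept on the baseline grid.
#' @param imputation optional `imputation_model` stored for prediction-time
#'   population-mean imputation.
#' @param seed seed for the lambda cross-validation folds.
#' @return list of class `stacked_model`: `coef`, `info`, `lambda`,
#'   `center`, `s0` (baseline grid), `flavor`, `boosted`, `imputation`,
#'   `variables`, `horizon`.
#' @export
fit_stacked <- function(cohort, mandatory = NULL, boosted = NULL, score = NULL,
                        lambda = NULL, flavor = c("basic", "full"),
                        horizon = 10, imputation = NULL, seed = 1L) {
  flavor <- match.arg(flavor)
  d <- cohort$data
  if (is.null(mandatory)) mandatory <- mandatory_vars(cohort$catalog)
  if (length(mandatory) == 0L) stop("no mandatory variables")
  X <- cohort_matrix(cohort, mandatory)
  if (flavor == "full") {
    if (is.null(boosted)) stop("flavor='full' requires a boosted model")
    if (is.null(score)) score <- boosted_score(boosted, cohort)
    X <- cbind(X, boost_score = score)
  }
  if (is.null(lambda)) {
    lambda <- cv_ridge_lambda(X, d$followup_years, d$event, seed = seed)
  }
  fit <- ridge_cox(X, d$followup_years, d$event, lambda)
  lp <- as.vector(X %*% fit$coef)
  ctr <- mean(lp)
  s0 <- breslow_baseline(lp, d$followup_years, d$event, ctr, horizon = horizon)
  structure(list(coef = fit$coef, info = fit$info, lambda = lambda,
                 center = ctr, s0 = s0, flavor = flavor,
                 boosted = if (flavor == "full") boosted else NULL,
                 imputation = imputation, variables = mandatory,
                 horizon = horizon),
            class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> flavor=%s, lambda=%.4g, %d coefficients\n",
              x$flavor, x$lambda, length(x$coef)))
  print(round(exp(x$coef), 3))
  invisible(x)
}

# linear predictor for new subjects (mean-imputes stored lab fields,
# absent-equals-zero for binary flags; errors on missing mandatory values)
stacked_lp <- function(model, newdata) {
  d <- if (inherits(newdata, "cohort_table")) newdata$data else as.data.frame(newdata)
  X <- matrix(NA_real_, nrow(d), length(model$variables),
              dimnames = list(NULL, model$variables))
  for (v in model$variables) {
    if (!v %in% names(d)) stop("missing mandatory feature: ", v)
    x <- as.numeric(d[[v]])
    if (anyNA(x) && !is.null(model$imputation) &&
        v %in% model$imputation$vars) {
      x[is.na(x)] <- unname(model$imputation$population_means[v])
    }
    X[, v] <- x
  }
  bad <- colnames(X)[colSums(is.na(X)) > 0]
  if (length(bad)) stop("missing mandatory feature after imputation: ",
                        paste(bad, collapse = ", "))
  lp <- as.vector(X %*% model$coef[model$variables])
  if (model$flavor == "full") {
    db <- d
    if (!is.null(model$imputation)) {
      for (v in intersect(model$imputation$vars, names(db))) {
        x <- as.numeric(db[[v]])
        x[is.na(x)] <- unname(model$imputation$population_means[v])
        db[[v]] <- x
      }
    }
    lp <- lp + model$coef["boost_score"] * boosted_score(model$boosted, db)
  }
  lp
}

#' Predict absolute risk at a horizon
#'
#' `risk = 1 - S0(horizon)^exp(lp - center)` with the stored Breslow
#' baseline `S0` and training-mean centring.
#'
#' @param model a `stacked_model`.
#' @param newdata a `cohort_table` or data frame of features.
#' @param horizon horizon in years (default: the model's).
#' @return numeric vector of risks in `[0, 1]`.
#' @export
predict_risk <- function(model, newdata, horizon = NULL) {
  horizon <- horizon %||% model$horizon
  lp <- stacked_lp(model, newdata)
  shift <- model$recal_shift %||% 0
  slope <- model$recal_slope %||% 1
  s0h <- baseline_surv_at(model$s0, horizon)
  H <- -log(s0h) * exp(shift)
  pmin(pmax(1 - exp(-H * exp(slope * (lp - model$center))), 0), 1)
}

#' Hazard-ratio table of a stacked model
#'
#' Hazard ratios, approximate Wald 95% confidence intervals and p-values
#' from the ridge-penalized information matrix. Because the penalty biases
#' the curvature, the intervals are approximate and flagged as such.
#'
#' @param model a `stacked_model`.
#' @param conf_level confidence level (default 0.95).
#' @return data frame of class `hazard_ratio_table` with columns `name`,
#'   `coef`, `hr`, `lower`, `upper`, `p`; attribute `approximate = TRUE`.
#' @export
hazard_ratios <- function(model, conf_level = 0.95) {
  se <- sqrt(diag(solve(model$info)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cf <- model$coef
  out <- data.frame(name = names(cf), coef = unname(cf),
                    hr = exp(unname(cf)),
                    lower = exp(unname(cf) - z * se),
                    upper = exp(unname(cf) + z * se),
                    p = 2 * stats::pnorm(-abs(unname(cf) / se)))
  attr(out, "approximate") <- TRUE
  class(out) <- c("hazard_ratio_table", "data.frame")
  out
}

#' Derive basic and full models from a raw cohort
#'
#' End-to-end derivation pipeline: eligibility screening, chained-equation
#' imputation (model fitted on the first completed dataset), LASSO
#' shortlisting (recorded, not enforced on the mandatory set), boosted
#' stage on all eligible variables with out-of-fold scores for stacking,
#' and the ridge-penalized stacked fit.
#'
#' @param cohort a `cohort_table` (may contain missing numerics).
#' @param flavor `"basic"` or `"full"`.
#' @param hp boosted-stage hyperparameters, or `"tune"` to grid-search.
#' @param lambda ridge penalty (`NULL` = CV).
#' @param seed integer seed.
#' @param horizon prediction horizon (years).
#' @param mice_m,mice_iter imputation settings.
#' @return a `stacked_model`.
#' @export
derive_model <- function(cohort, flavor = c("basic", "full"),
                         hp = boost_hyperparams(), lambda = NULL, seed = 1L,
                         horizon = 10, mice_m = 1, mice_iter = 5) {
  flavor <- match.arg(flavor)
  elig <- screen_variables(cohort)
  vars <- eligible_vars(elig)
  imp <- mice_impute(cohort, m = mice_m, iterations = mice_iter, seed = seed,
                     vars = vars)
  completed <- imp$completed[[1]]
  boosted <- NULL; score <- NULL
  if (flavor == "full") {
    if (identical(hp, "tune")) {
      hp <- tune_boosted(completed, vars, seed = seed)
    }
    boosted <- fit_boosted(completed, vars, hp, seed = seed)
    score <- oof_boosted_scores(completed, vars, hp, seed = seed)
  }
  fit_stacked(completed, boosted = boosted, score = score, lambda = lambda,
              flavor = flavor, horizon = horizon, imputation = imp$model,
              seed = seed)
}
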