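#' Screen variables for model eligibility
#'
#' Numeric variables are eligible when their missing rate is below
#' `missing_threshold`; binary variables when their prevalence ("event
#' rate" of the flag) exceeds `event_threshold`. Mandatory and
#' mandatory-imputable variables are always eligible.
#'
#' @param cohort a `cohort_table`.
#' @param missing_threshold numeric-variable missing-rate cutoff (default 0.10).
#' @param event_threshold binary-variable prevalence cutoff (default 0.01).
#' @return data frame of class `eligibility_report`: per variable the
#'   missing rate or prevalence, the eligibility flag and a reason string.
#' @export
screen_variables <- function(cohort, missing_threshold = 0.10,
                             event_threshold = 0.01) {
  cat <- cohort$catalog
  d <- cohort$data
  rep <- lapply(seq_len(nrow(cat)), function(i) {
    v <- cat$name[i]
    x <- d[[v]]
    forced <- cat$mandatory[i] || cat$mandatory_imputable[i]
    if (cat$kind[i] == "numeric") {
      mr <- mean(is.na(x))
      ok <- mr < missing_threshold
      data.frame(name = v, kind = "numeric", rate = mr,
                 eligible = ok || forced,
                 reason = if (forced && !ok) "mandatory override"
                          else if (ok) sprintf("missing rate %.1f%% < %.0f%%",
                                               100 * mr, 100 * missing_threshold)
                          else sprintf("missing rate %.1f%% >= %.0f%%",
                                       100 * mr, 100 * missing_threshold))
    } else {
      pr <- mean(x == 1, na.rm = TRUE)
      if (is.nan(pr)) pr <- 0
      ok <- pr > event_threshold
      data.frame(name = v, kind = "binary", rate = pr,
                 eligible = ok || forced,
                 reason = if (forced && !ok) "mandatory override"
                          else if (ok) sprintf("event rate %.1f%% > %.0f%%",
                                               100 * pr, 100 * event_threshold)
                          else sprintf("event rate %.1f%% <= %.0f%%",
                                       100 * pr, 100 * event_threshold))
    }
  })
  out <- do.call(rbind, rep)
  class(out) <- c("eligibility_report", "data.frame")
  out
}

#' @rdname screen_variables
#' @param report an `eligibility_report`.
#' @export
eligible_vars <- function(report) report$name[report$eligible]

# draw regression coefficients and residual sd from the (approximate)
# posterior of a ridge-stabilized linear model; used by the PMM sampler
bayes_lm_draw <- function(X, y, ridge = 1e-6) {
  p <- ncol(X)
  XtX <- crossprod(X) + diag(ridge * pmax(diag(crossprod(X)) / nrow(X), 1e-8), p)
  Xty <- crossprod(X, y)
  R <- chol(XtX)
  bhat <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  df <- max(nrow(X) - p, 1)
  s2 <- sum((y - X %*% bhat)^2) / df
  s2_draw <- s2 * df / stats::rchisq(1, df)
  bstar <- bhat + backsolve(R, stats::rnorm(p)) * sqrt(s2_draw)
  list(bhat = bhat, bstar = bstar)
}

#' Chained-equation imputation with predictive mean matching
#'
#' Iteratively imputes each incomplete numeric variable from a linear model
#' on all other eligible variables, using Bayesian parameter draws and
#' predictive mean matching (donor pool of `donors` nearest observed
#' cases), producing `m` completed datasets. Binary variables enter the
#' conditional models as complete predictors (missing flags read as 0) and
#' are never imputed. Observed values are never altered.
#'
#' @param cohort a `cohort_table` with missing numeric values.
#' @param m number of completed datasets (default 5).
#' @param iterations chained iterations per dataset (default 10).
#' @param seed integer seed; results are reproducible given it.
#' @param donors predictive-mean-matching donor pool size (default 5).
#' @param vars variables to impute and to use as predictors; default = all
#'   eligible variables under the default screening thresholds.
#' @return list with `completed` (list of `m` completed `cohort_table`s)
#'   and `model` (an `imputation_model`: per-variable specs, the
#'   derivation-cohort population means over observed values, `m`,
#'   `iterations`, `seed`).
#' @export
mice_impute <- function(cohort, m = 5, iterations = 10, seed = 1L,
                        donors = 5, vars = NULL) {
  cat <- cohort$catalog
  d <- cohort$data
  if (is.null(vars)) vars <- eligible_vars(screen_variables(cohort))
  num_vars <- intersect(vars, cat$name[cat$kind == "numeric"])
  bin_vars <- intersect(vars, cat$name[cat$kind == "binary"])
  target <- num_vars[vapply(num_vars, function(v) anyNA(d[[v]]), TRUE)]
  for (v in target) {
    if (all(is.na(d[[v]]))) stop("variable '", v, "' is 100% missing; cannot initialize")
  }
  pop_means <- vapply(num_vars, function(v) mean(d[[v]], na.rm = TRUE), 0)
  model <- structure(list(vars = num_vars, imputed = target,
                          population_means = pop_means, m = m,
                          iterations = iterations, donors = donors,
                          seed = as.integer(seed)),
                     class = "imputation_model")
  if (length(target) == 0L) {
    return(list(completed = replicate(m, cohort, simplify = FALSE), model = model))
  }

  set.seed(as.integer(seed))
  pred_base <- c(num_vars, bin_vars)
  Xbin <- if (length(bin_vars)) {
    xb <- as.matrix(d[bin_vars]); xb[is.na(xb)] <- 0; xb
  } else NULL

  completed <- vector("list", m)
  for (im in seq_len(m)) {
    W <- as.matrix(d[num_vars])
    # initialize missing cells with random observed draws
    for (v in target) {
      isna <- is.na(W[, v])
      W[isna, v] <- sample(W[!isna, v], sum(isna), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in target) {
        isna <- is.na(d[[v]])
        others <- setdiff(num_vars, v)
        X <- cbind(1, W[, others, drop = FALSE], Xbin)
        # drop collinear columns (constant or duplicated) with a warning
        keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                              function(col) stats::sd(col) > 1e-10))
        X <- X[, keep, drop = FALSE]
        qrX <- qr(X)
        if (qrX$rank < ncol(X)) {
          warning("collinear predictors dropped while imputing '", v, "'")
          X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
        }
        y_obs <- d[[v]][!isna]
        dr <- bayes_lm_draw(X[!isna, , drop = FALSE], y_obs)
        yhat_obs <- as.vector(X[!isna, , drop = FALSE] %*% dr$bhat)
        yhat_mis <- as.vector(X[isna, , drop = FALSE] %*% dr$bstar)
        # PMM: sample one of the `donors` nearest observed cases
        ord <- order(yhat_obs)
        yhat_srt <- yhat_obs[ord]; yobs_srt <- y_obs[ord]
        pos <- findInterval(yhat_mis, yhat_srt)
        nobs <- length(yobs_srt)
        imp <- vapply(seq_along(yhat_mis), function(j) {
          ctr <- pos[j]
          lo <- max(1L, ctr - donors); hi <- min(nobs, ctr + donors)
          cand <- lo:hi
          dd <- abs(yhat_srt[cand] - yhat_mis[j])
          cand <- cand[order(dd)][seq_len(min(donors, length(cand)))]
          yobs_srt[cand[sample.int(length(cand), 1L)]]
        }, 0)
        W[isna, v] <- imp
      }
    }
    dc <- d
    for (v in target) dc[[v]] <- W[, v]
    ci <- cohort
    ci$data <- dc
    completed[[im]] <- ci
  }
  list(completed = completed, model = model)
}

#' Population-mean imputation for prediction time
#'
#' Fills missing numeric fields of a single subject's feature map with the
#' derivation-cohort population means stored in the imputation model.
#' Observed values and binary flags are untouched.
#'
#' @param features named list or one-row data frame of feature values.
#' @param model an `imputation_model` from [mice_impute()].
#' @return completed named list of features.
#' @export
mean_impute <- function(features, model) {
  stopifnot(inherits(model, "imputation_model"))
  f <- as.list(features)
  for (v in names(f)) {
    if (v %in% model$vars && (is.null(f[[v]]) || is.na(f[[v]]))) {
      f[[v]] <- unname(model$population_means[v])
    }
  }
  f
}

#' LASSO shortlisting of risk variables
#'
#' Fits an L1-penalized Cox model over a penalty path, chooses the penalty
#' by k-fold cross-validated partial likelihood, refits the
#' nonzero-coefficient variables in an unpenalized Cox model, and selects
#' the variables with refit p-value below `alpha`, plus all mandatory
#' variables.
#'
#' @param cohort a completed `cohort_table` (no missingness among candidates).
#' @param candidates candidate variable names; default = all eligible.
#' @param seed integer seed for the cross-validation folds.
#' @param alpha refit p-value cutoff (default 0.05).
#' @param nfolds CV folds (default 5).
#' @param lambda_rule `"lambda.min"` (default) or `"lambda.1se"`.
#' @return list of class `selection_report`: `selected`, `lasso_nonzero`,
#'   `refit` (coefficients and p-values), `lambda`, `mandatory`.
#' @export
lasso_screen <- function(cohort, candidates = NULL, seed = 1L, alpha = 0.05,
                         nfolds = 5, lambda_rule = "lambda.min") {
  d <- cohort$data
  if (sum(d$event) == 0L) stop("no events; cannot run penalized Cox")
  if (is.null(candidates)) candidates <- eligible_vars(screen_variables(cohort))
  candidates <- sort(candidates)   # canonical order: selection must not depend on it
  X <- cohort_matrix(cohort, candidates)
  if (anyNA(X)) stop("candidates contain missing values; impute first")
  y <- survival::Surv(d$followup_years, d$event)
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1, foldid = foldid)
  lam <- cvfit[[lambda_rule]]
  cf <- as.matrix(stats::coef(cvfit, s = lam))
  nonzero <- rownames(cf)[cf[, 1] != 0]
  mand <- mandatory_vars(cohort$catalog)
  if (length(nonzero) == 0L) {
    warning("penalty path collapsed to the empty model; returning mandatory-only")
    return(structure(list(selected = intersect(mand, candidates),
                          lasso_nonzero = character(0), refit = NULL,
                          lambda = lam, mandatory = mand),
                     class = "selection_report"))
  }
  refit_df <- data.frame(d[c("followup_years", "event")], X[, nonzero, drop = FALSE])
  fml <- stats::as.formula(paste("survival::Surv(followup_years, event) ~",
                                 paste(sprintf("`%s`", nonzero), collapse = " + ")))
  refit <- survival::coxph(fml, data = refit_df)
  sm <- summary(refit)$coefficients
  pvals <- sm[, "Pr(>|z|)"]
  names(pvals) <- gsub("`", "", rownames(sm))
  sig <- names(pvals)[pvals < alpha]
  selected <- sort(union(sig, intersect(mand, candidates)))
  structure(list(selected = selected, lasso_nonzero = nonzero,
                 refit = data.frame(name = names(pvals),
                                    coef = unname(sm[, "coef"]),
                                    p = unname(pvals)),
                 lambda = lam, mandatory = mand),
            class = "selection_report")
}
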