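#' Cox partial-likelihood objective (gradient and Hessian)
#'
#' First and second derivatives of the negative log partial likelihood with
#' respect to each subject's linear predictor, with Breslow handling of
#' tied event times. These drive the gradient-boosting stage: for subject
#' j, the gradient is `exp(lp_j) * sum_{event times t_i <= t_j} d_i / S0(t_i)
#' - event_j` where `S0(t)` is the risk-set sum of `exp(lp)`, and the
#' Hessian is the corresponding diagonal second derivative. Gradients sum
#' to zero (score identity).
#'
#' @param lp per-subject linear predictor (finite).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @return list with `grad` and `hess`, both length `n`.
#' @export
cox_objective <- function(lp, times, events) {
  n <- length(lp)
  stopifnot(length(times) == n, length(events) == n)
  if (!all(is.finite(lp))) stop("non-finite linear predictor")
  if (sum(events) == 0) stop("no events; partial likelihood undefined")
  ord <- order(times, decreasing = TRUE)
  w <- exp(lp[ord])
  t_s <- times[ord]
  e_s <- events[ord]
  cum_w <- cumsum(w)
  # risk-set denominator at each (tied) time = cumulative sum at the last
  # index sharing that time in the descending sort
  last_idx <- cumsum(tabulate(match(t_s, unique(t_s))))
  grp <- match(t_s, unique(t_s))
  S0 <- cum_w[last_idx][grp]
  d_i <- as.vector(rowsum(e_s, grp))          # events per unique time
  # cumulative hazard increments ordered by descending time
  inc <- d_i / cum_w[last_idx]
  inc2 <- d_i / cum_w[last_idx]^2
  # for subject j, sum over event times <= t_j: reverse cumulative sums
  H1 <- rev(cumsum(rev(inc)))[grp]
  H2 <- rev(cumsum(rev(inc2)))[grp]
  grad_s <- w * H1 - e_s
  hess_s <- pmax(w * H1 - w^2 * H2, 1e-16)
  grad <- numeric(n); hess <- numeric(n)
  grad[ord] <- grad_s
  hess[ord] <- hess_s
  list(grad = grad, hess = hess)
}

# negative log partial likelihood (Breslow), for tests and tuning
neg_log_partial_lik <- function(lp, times, events) {
  ord <- order(times, decreasing = TRUE)
  w <- exp(lp[ord]); t_s <- times[ord]; e_s <- events[ord]
  grp <- match(t_s, unique(t_s))
  last_idx <- cumsum(tabulate(grp))
  cum_w <- cumsum(w)
  S0_u <- cum_w[last_idx]
  d_u <- as.vector(rowsum(e_s, grp))
  lp_sum_u <- as.vector(rowsum(lp[ord] * e_s, grp))
  -sum(lp_sum_u - d_u * log(S0_u))
}

#' Hyperparameters for the boosted Cox stage
#'
#' @param depth maximum tree depth.
#' @param learning_rate shrinkage per boosting round.
#' @param rounds number of boosting rounds.
#' @param subsample row subsampling fraction per round.
#' @param lambda L2 penalty on leaf weights.
#' @return list of class `boost_hyperparams`.
#' @export
boost_hyperparams <- function(depth = 3, learning_rate = 0.1, rounds = 100,
                              subsample = 0.8, lambda = 1) {
  stopifnot(depth >= 1, learning_rate > 0, rounds >= 0,
            subsample > 0, subsample <= 1, lambda >= 0)
  structure(list(depth = as.integer(depth), learning_rate = learning_rate,
                 rounds = as.integer(rounds), subsample = subsample,
                 lambda = lambda),
            class = "boost_hyperparams")
}

#' Default hyperparameter grid for [tune_boosted()]
#' @return list of `boost_hyperparams`.
#' @export
default_boost_grid <- function() {
  grid <- expand.grid(depth = c(2, 3, 4), learning_rate = c(0.05, 0.1),
                      rounds = c(100, 300), subsample = 0.8)
  lapply(seq_len(nrow(grid)), function(i) do.call(boost_hyperparams, as.list(grid[i, ])))
}

xgb_cox_obj <- function(times, events, loss_hook = NULL) {
  force(times); force(events)
  if (is.null(loss_hook)) {
    function(preds, dtrain) {
      o <- cox_objective(preds, times, events)
      list(grad = o$grad, hess = o$hess)
    }
  } else {
    function(preds, dtrain) loss_hook(preds, times, events)
  }
}

#' Fit a gradient-boosted Cox model
#'
#' Grows an xgboost tree ensemble against [cox_objective()] (or a custom
#' survival loss supplied through `loss_hook`). The returned score is the
#' ensemble margin centred to its training mean, in log-relative-hazard
#' units. Missing covariate values are routed through the trees' learned
#' default directions.
#'
#' @param cohort a `cohort_table` (complete for the listed variables after
#'   imputation; `NA`s are tolerated and handled natively by the trees).
#' @param variables training variable names.
#' @param hp a [boost_hyperparams()] object.
#' @param seed integer seed (subsampling).
#' @param loss_hook optional `function(preds, times, events)` returning
#'   `list(grad, hess)`, replacing the default Cox objective.
#' @return list of class `boosted_cox_model`: the booster (raw bytes),
#'   `variables`, `hp`, the centring `offset`.
#' @export
fit_boosted <- function(cohort, variables, hp = boost_hyperparams(),
                        seed = 1L, loss_hook = NULL) {
  d <- cohort$data
  X <- cohort_matrix(cohort, variables)
  if (hp$rounds == 0L) {
    return(structure(list(raw = NULL, variables = variables, hp = hp,
                          offset = 0), class = "boosted_cox_model"))
  }
  dtr <- xgboost::xgb.DMatrix(X, label = ifelse(d$event == 1,
                                                d$followup_years,
                                                -d$followup_years),
                              nthread = 1)
  params <- xgboost::xgb.params(
    max_depth = hp$depth, learning_rate = hp$learning_rate,
    subsample = hp$subsample, reg_lambda = hp$lambda,
    base_score = 0, nthread = 1, seed = as.integer(seed)
  )
  bst <- xgboost::xgb.train(params = params, data = dtr, nrounds = hp$rounds,
                            objective = xgb_cox_obj(d$followup_years, d$event,
                                                    loss_hook),
                            verbose = 0)
  raw <- xgboost::xgb.save.raw(bst)
  offset <- mean(predict(bst, X))
  structure(list(raw = raw, variables = variables, hp = hp, offset = offset),
            class = "boosted_cox_model")
}

#' @rdname fit_boosted
#' @param model a `boosted_cox_model`.
#' @param newdata a `cohort_table` or data frame with the training variables.
#' @export
boosted_score <- function(model, newdata) {
  d <- if (inherits(newdata, "cohort_table")) newdata$data else newdata
  X <- matrix(NA_real_, nrow(d), length(model$variables),
              dimnames = list(NULL, model$variables))
  for (v in model$variables) X[, v] <- as.numeric(d[[v]])
  if (is.null(model$raw)) return(rep(0, nrow(X)))
  bst <- xgboost::xgb.load.raw(model$raw)
  predict(bst, X) - model$offset
}

#' Out-of-fold boosted scores
#'
#' K-fold cross-fitting of the boosted stage: each subject's score comes
#' from the ensemble trained on the other folds, limiting optimism when the
#' score is stacked into the penalized Cox model.
#'
#' @inheritParams fit_boosted
#' @param folds number of folds (default 5).
#' @return numeric vector of centred out-of-fold scores.
#' @export
oof_boosted_scores <- function(cohort, variables, hp = boost_hyperparams(),
                               seed = 1L, folds = 5, loss_hook = NULL) {
  d <- cohort$data
  n <- nrow(d)
  set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), n))
  score <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- cohort
    tr$data <- d[fold_id != f, , drop = FALSE]
    m <- fit_boosted(tr, variables, hp, seed = seed + f, loss_hook = loss_hook)
    score[fold_id == f] <- boosted_score(m, d[fold_id == f, , drop = FALSE])
  }
  score - mean(score)
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustively evaluates a grid of hyperparameter settings by mean
#' out-of-fold Harrell's C of the boosted score; ties are broken toward
#' fewer rounds, then shallower trees.
#'
#' @inheritParams fit_boosted
#' @param grid list of [boost_hyperparams()] (default [default_boost_grid()]).
#' @param folds CV folds (default 5).
#' @return the winning `boost_hyperparams`, with the score table in
#'   attribute `"results"`.
#' @export
tune_boosted <- function(cohort, variables, grid = default_boost_grid(),
                         folds = 5, seed = 1L) {
  if (length(grid) == 0L) stop("empty hyperparameter grid")
  d <- cohort$data
  cstat <- vapply(grid, function(hp) {
    sc <- oof_boosted_scores(cohort, variables, hp, seed = seed, folds = folds)
    harrells_c(sc, d$followup_years, d$event)
  }, 0)
  rounds <- vapply(grid, `[[`, 0L, "rounds")
  depth <- vapply(grid, `[[`, 0L, "depth")
  best <- order(-cstat, rounds, depth)[1L]
  out <- grid[[best]]
  attr(out, "results") <- data.frame(
    depth = depth, rounds = rounds,
    learning_rate = vapply(grid, `[[`, 0, "learning_rate"),
    subsample = vapply(grid, `[[`, 0, "subsample"),
    oof_c = cstat)
  out
}

#' Additive per-variable attributions of the boosted score
#'
#' Exact tree-ensemble Shapley values (TreeSHAP) for each subject: a base
#' value plus one contribution per variable, summing to the subject's
#' boosted score. Per-cohort mean absolute contributions give a feature
#' importance ranking.
#'
#' @param model a `boosted_cox_model`.
#' @param newdata a `cohort_table` or data frame.
#' @return matrix `n x (p+1)`; the last column `BIAS` is the base value
#'   minus the model's centring offset is applied so that
#'   `rowSums(result) == boosted_score(model, newdata)`.
#' @export
attribute <- function(model, newdata) {
  d <- if (inherits(newdata, "cohort_table")) newdata$data else newdata
  X <- matrix(NA_real_, nrow(d), length(model$variables),
              dimnames = list(NULL, model$variables))
  for (v in model$variables) X[, v] <- as.numeric(d[[v]])
  if (is.null(model$raw)) {
    out <- matrix(0, nrow(X), ncol(X) + 1,
                  dimnames = list(NULL, c(model$variables, "BIAS")))
    return(out)
  }
  bst <- xgboost::xgb.load.raw(model$raw)
  ctr <- predict(bst, X, predcontrib = TRUE)
  colnames(ctr) <- c(model$variables, "BIAS")
  ctr[, "BIAS"] <- ctr[, "BIAS"] - model$offset
  ctr
}
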