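#' Harrell's concordance statistic
#'
#' Probability that, among usable subject pairs (the shorter follow-up time
#' is an event), the subject with the higher predicted risk fails first;
#' ties in predicted risk count one half.
#'
#' @param risk predicted risk scores (any monotone scale).
#' @param times,events follow-up times and 0/1 indicators.
#' @return C in `[0, 1]`.
#' @export
harrells_c <- function(risk, times, events) {
  stopifnot(length(risk) == length(times), length(times) == length(events))
  if (sum(events) == 0) stop("no usable pairs: no events")
  fit <- survival::concordance(survival::Surv(times, events) ~ risk,
                               reverse = TRUE)
  unname(fit$concordance)
}

#' Bootstrap mean and percentile confidence interval of a metric
#'
#' Resamples subjects with replacement `B` times, recomputes the metric on
#' each resample, and returns the mean with a percentile interval.
#'
#' @param metric function taking a resampled `cohort_table` (or data
#'   frame, whichever was supplied) and returning a scalar.
#' @param cohort a `cohort_table` or data frame.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf_level confidence level (default 0.95).
#' @return list: `mean`, `lower`, `upper`, `values` (length `B`).
#' @export
bootstrap_metric <- function(metric, cohort, B = 1000, seed = 1L,
                             conf_level = 0.95) {
  if (B < 2) stop("B must be at least 2")
  is_ct <- inherits(cohort, "cohort_table")
  d <- if (is_ct) cohort$data else cohort
  n <- nrow(d)
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- d[idx, , drop = FALSE]
    if (is_ct) {
      ct <- cohort; ct$data <- res
      metric(ct)
    } else metric(res)
  }, 0)
  a <- (1 - conf_level) / 2
  qs <- stats::quantile(vals, c(a, 1 - a), names = FALSE)
  list(mean = mean(vals), lower = qs[1], upper = qs[2], values = vals)
}

#' Repeated stratified k-fold cross-validation
#'
#' Event-stratified folds, reshuffled every repeat; each repeat returns the
#' pooled out-of-fold metric.
#'
#' @param cohort a `cohort_table`.
#' @param fit function(train_cohort) returning a model object.
#' @param score function(model, test_cohort) returning per-subject risk.
#' @param metric function(risk, times, events) returning a scalar (default
#'   [harrells_c()]).
#' @param k folds (default 10); must not exceed the number of events.
#' @param repeats repeats (default 100).
#' @param seed integer seed.
#' @return numeric vector, one pooled out-of-fold metric per repeat.
#' @export
repeated_cv <- function(cohort, fit, score, metric = harrells_c, k = 10,
                        repeats = 100, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  d <- cohort$data
  if (sum(d$event) < k) stop("fewer events than folds")
  set.seed(as.integer(seed))
  vapply(seq_len(repeats), function(r) {
    fid <- integer(nrow(d))
    for (g in c(0, 1)) {
      idx <- which(d$event == g)
      fid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    risk <- numeric(nrow(d))
    for (f in seq_len(k)) {
      tr <- cohort; tr$data <- d[fid != f, , drop = FALSE]
      te <- cohort; te$data <- d[fid == f, , drop = FALSE]
      m <- fit(tr)
      risk[fid == f] <- score(m, te)
    }
    metric(risk, d$followup_years, d$event)
  }, 0)
}

#' Decile calibration table
#'
#' Ranks subjects by predicted risk, splits them into `groups` equal-count
#' groups (subjects sharing a predicted risk stay together), and pairs each
#' group's mean predicted risk with the Kaplan-Meier observed risk at the
#' horizon.
#'
#' @param risk predicted risks at the horizon.
#' @param times,events follow-up data.
#' @param horizon horizon in years.
#' @param groups number of groups (default 10).
#' @return data frame of class `calibration_table`: per group `n`,
#'   `mean_predicted`, `km_observed`, `km_lower`, `km_upper`.
#' @export
decile_calibration <- function(risk, times, events, horizon = 10, groups = 10) {
  n <- length(risk)
  if (n < groups) stop("need at least ", groups, " subjects")
  if (length(unique(risk)) < 2) {
    stop("degenerate risk vector: fewer than 2 distinct predicted risks")
  }
  grp <- ceiling(groups * rank(risk, ties.method = "min") / n)
  grp <- match(grp, sort(unique(grp)))   # compact labels after tie merging
  if (length(unique(grp)) < groups) {
    warning("ties forced coarser grouping: ", length(unique(grp)), " groups")
  }
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    i <- grp == g
    km <- km_survival(times[i], events[i], horizon)
    data.frame(group = g, n = sum(i), mean_predicted = mean(risk[i]),
               km_observed = 1 - km$surv, km_lower = 1 - km$upper,
               km_upper = 1 - km$lower)
  }))
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Calibration slope from a calibration table
#'
#' Ordinary least-squares slope of observed risk on mean predicted risk
#' across the risk groups; 1 is ideal.
#'
#' @param table a `calibration_table`.
#' @return the slope.
#' @export
calibration_slope <- function(table) {
  if (nrow(table) < 2 || stats::sd(table$mean_predicted) < 1e-12) {
    stop("degenerate predictor spread across groups")
  }
  unname(stats::coef(stats::lm(km_observed ~ mean_predicted, data = table))[2])
}

#' Calibration-in-the-large
#'
#' Overall Kaplan-Meier observed risk at the horizon minus the mean
#' predicted risk; 0 is ideal (positive = under-prediction).
#'
#' @inheritParams decile_calibration
#' @return scalar.
#' @export
calibration_in_the_large <- function(risk, times, events, horizon = 10) {
  km <- km_survival(times, events, horizon)
  (1 - km$surv) - mean(risk)
}

#' IPCW Brier score at a horizon
#'
#' Inverse-probability-of-censoring-weighted squared error at the horizon:
#' subjects with an event before the horizon contribute `(1 - risk)^2`
#' weighted by `1/G(T-)`, subjects event-free at the horizon contribute
#' `risk^2` weighted by `1/G(horizon)`, subjects censored before the
#' horizon are weighted out; `G` is the Kaplan-Meier estimate of the
#' censoring distribution. With no censoring this reduces to the plain
#' mean squared error.
#'
#' @inheritParams decile_calibration
#' @return the Brier score.
#' @export
brier_score <- function(risk, times, events, horizon = 10) {
  n <- length(risk)
  cen_fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  G_at <- function(t) {
    i <- findInterval(t, cen_fit$time)
    ifelse(i == 0L, 1, cen_fit$surv[pmax(i, 1L)])
  }
  G_left <- function(t) G_at(t - 1e-9)
  contrib <- numeric(n)
  ev_before <- events == 1 & times <= horizon
  at_risk <- times > horizon
  Gt <- G_left(times[ev_before])
  Gh <- G_at(horizon)
  if ((any(ev_before) && any(Gt <= 0)) || (any(at_risk) && Gh <= 0)) {
    stop("censoring survival reaches 0 before the horizon; shorten the horizon")
  }
  contrib[ev_before] <- (1 - risk[ev_before])^2 / Gt
  contrib[at_risk] <- (risk[at_risk])^2 / Gh
  sum(contrib) / n
}

#' Decision-curve analysis (net benefit)
#'
#' Net benefit of treating subjects whose predicted risk meets each
#' threshold `p_t`: `TP/n - FP/n * p_t/(1-p_t)`, with true/false positives
#' among flagged subjects estimated by the Kaplan-Meier event rate at the
#' horizon within the flagged group (censoring-aware). Includes treat-all
#' and treat-none reference policies.
#'
#' @inheritParams decile_calibration
#' @param thresholds threshold grid in (0,1); values >= 1 are dropped.
#' @return data frame of class `net_benefit_curve`: `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(risk, times, events, horizon = 10,
                           thresholds = seq(0.01, 0.50, by = 0.01)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(risk)
  km_all <- km_survival(times, events, horizon)
  prev <- 1 - km_all$surv
  out <- do.call(rbind, lapply(thresholds, function(pt) {
    wt <- pt / (1 - pt)
    flag <- risk >= pt
    if (any(flag)) {
      kmf <- km_survival(times[flag], events[flag], horizon)
      rf <- 1 - kmf$surv
      pf <- mean(flag)
      nb <- pf * rf - pf * (1 - rf) * wt
    } else nb <- 0
    data.frame(threshold = pt, nb_model = nb,
               nb_all = prev - (1 - prev) * wt, nb_none = 0)
  }))
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Recalibrate a stacked model to a target cohort
#'
#' Estimates an intercept shift on the log-cumulative-hazard scale and a
#' slope multiplier on the centred linear predictor from the target
#' cohort, and accepts the update only if neither the calibration slope's
#' distance from 1 nor the absolute calibration-in-the-large worsens.
#'
#' @param model a `stacked_model`.
#' @param cohort target `cohort_table`.
#' @param horizon horizon in years.
#' @return list of class `recalibration_result`: `shift`, `slope_mult`,
#'   `before`/`after` (each with `slope` and `citl`), `accepted`, and
#'   `model` (updated when accepted, otherwise the original).
#' @export
recalibrate <- function(model, cohort, horizon = 10) {
  d <- cohort$data
  if (sum(d$event) == 0) stop("degenerate target cohort: no events")
  lp <- stacked_lp(model, cohort) - model$center
  risk0 <- predict_risk(model, cohort, horizon)
  cal0 <- decile_calibration(risk0, d$followup_years, d$event, horizon)
  before <- list(slope = calibration_slope(cal0),
                 citl = calibration_in_the_large(risk0, d$followup_years,
                                                 d$event, horizon))
  # slope multiplier: unpenalized Cox on the centred linear predictor
  sfit <- survival::coxph(survival::Surv(followup_years, event) ~ lp,
                          data = data.frame(d[c("followup_years", "event")],
                                            lp = lp))
  b <- unname(stats::coef(sfit))
  # intercept: match the expected event count under the model's own
  # baseline shape, H_target = exp(shift) * H0
  H0T <- -log(baseline_surv_at(model$s0, d$followup_years))
  shift <- log(sum(d$event) / sum(H0T * exp(b * lp)))
  cand <- model
  cand$recal_shift <- (model$recal_shift %||% 0) + shift
  cand$recal_slope <- (model$recal_slope %||% 1) * b
  risk1 <- predict_risk(cand, cohort, horizon)
  cal1 <- decile_calibration(risk1, d$followup_years, d$event, horizon)
  after <- list(slope = calibration_slope(cal1),
                citl = calibration_in_the_large(risk1, d$followup_years,
                                                d$event, horizon))
  accepted <- abs(after$slope - 1) <= abs(before$slope - 1) &&
    abs(after$citl) <= abs(before$citl)
  structure(list(shift = shift, slope_mult = b, before = before,
                 after = after, accepted = accepted,
                 model = if (accepted) cand else model),
            class = "recalibration_result")
}

#' Validate a model on a cohort
#'
#' Computes the full validation report: bootstrap Harrell's C, calibration
#' slope, calibration-in-the-large, IPCW Brier score, the decile
#' calibration table and the net-benefit curve.
#'
#' @param model a `stacked_model` (or any object accepted by `predictor`).
#' @param cohort a `cohort_table`.
#' @param horizon horizon in years.
#' @param B bootstrap replicates for the C interval (default 200).
#' @param seed integer seed.
#' @param predictor function(model, cohort) returning per-subject risk;
#'   default [predict_risk()].
#' @return list of class `validation_report`.
#' @export
validate_model <- function(model, cohort, horizon = 10, B = 200, seed = 1L,
                           predictor = predict_risk) {
  d <- cohort$data
  risk <- predictor(model, cohort)
  cboot <- bootstrap_metric(function(res) {
    i <- match(res$data$subject_id, d$subject_id)
    harrells_c(risk[i], res$data$followup_years, res$data$event)
  }, cohort, B = B, seed = seed)
  cal <- decile_calibration(risk, d$followup_years, d$event, horizon)
  structure(list(
    c_mean = cboot$mean, c_lower = cboot$lower, c_upper = cboot$upper,
    c_point = harrells_c(risk, d$followup_years, d$event),
    calibration_slope = calibration_slope(cal),
    citl = calibration_in_the_large(risk, d$followup_years, d$event, horizon),
    brier = brier_score(risk, d$followup_years, d$event, horizon),
    calibration = cal,
    decision = decision_curve(risk, d$followup_years, d$event, horizon),
    metadata = list(B = B, seed = seed, horizon = horizon, n = nrow(d))
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("C = %.3f (%.3f-%.3f), slope = %.3f, CITL = %+.4f, Brier = %.4f\n",
              x$c_mean, x$c_lower, x$c_upper, x$calibration_slope, x$citl,
              x$brier))
  invisible(x)
}

#' Compare several models on one cohort
#'
#' @param models named list of `stacked_model`s (or objects usable by
#'   `predictor`).
#' @inheritParams validate_model
#' @return data frame, one row per model, with attribute `"reports"`.
#' @export
compare_models <- function(models, cohort, horizon = 10, B = 200, seed = 1L,
                           predictor = predict_risk) {
  reports <- lapply(models, validate_model, cohort = cohort,
                    horizon = horizon, B = B, seed = seed,
                    predictor = predictor)
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, c = r$c_mean, c_lower = r$c_lower,
               c_upper = r$c_upper, slope = r$calibration_slope,
               citl = r$citl, brier = r$brier)
  }))
  attr(out, "reports") <- reports
  out
}
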