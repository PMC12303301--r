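#' Assemble an analysis cohort from longitudinal records
#'
#' Applies the entry, censoring and exclusion rules of a primary-prevention
#' survival study to a long-format record stream. Each subject enters at
#' their first entry-marker record (e.g. first lipid test). Follow-up ends
#' at the earliest of the first outcome record, death, or the study end
#' date; the event indicator is 1 iff the outcome is the earliest. Subjects
#' are excluded when the outcome occurs strictly before entry, on the entry
#' day itself (zero follow-up), when death falls on or before entry, when
#' any record matches an exclusion codelist, or when they have no
#' entry-marker record at all. Exclusions are tallied in a ledger.
#'
#' @param records data frame of longitudinal records with columns
#'   `subject_id`, `time` (integer days since an epoch), `channel`, `code`,
#'   `value` (numeric, `NA` outside lab/vitals channels).
#' @param codelists list of [codelist()] objects. Exactly the codelists with
#'   role `entry_marker`, `outcome_component` and `exclusion` are used.
#' @param config list of cohort rules: `study_end` (day, required),
#'   `min_age` (optional; applied when an `age` feature is extracted),
#'   `outcome_priority` (optional character vector ordering outcome
#'   components for same-day ties; default = order of the codelists),
#'   `features` (optional named list mapping variable name to a list with
#'   `channel`, `patterns`, and `kind`; numeric features take the most
#'   recent lab/vitals value on or before entry, binary features flag any
#'   matching record on or before entry).
#' @param catalog optional `variable_catalog` for the extracted features; a
#'   minimal catalog is built from `config$features` when omitted.
#' @return A `cohort_table` with extra columns `entry_time` and
#'   `event_component`, plus attribute `exclusion_ledger` (named integer
#'   vector) retrievable with [exclusion_ledger()].
#' @seealso [summarize_cohort()], [km_survival()]
#' @export
build_cohort <- function(records, codelists, config, catalog = NULL) {
  stopifnot(is.data.frame(records))
  req <- c("subject_id", "time", "channel", "code")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (is.null(config$study_end)) stop("config$study_end is required")
  roles <- vapply(codelists, function(cl) cl$role, "")
  entry_cl <- codelists[roles == "entry_marker"]
  outcome_cl <- codelists[roles == "outcome_component"]
  excl_cl <- codelists[roles == "exclusion"]
  if (length(entry_cl) == 0L) stop("configuration error: no entry_marker codelist")
  if (length(outcome_cl) == 0L) stop("configuration error: no outcome codelist")

  rec <- data.table::as.data.table(records)
  match_cl <- function(cl) {
    hit <- rec$channel == cl$channel &
      Reduce(`|`, lapply(cl$patterns, function(p) startsWith(rec$code, p)))
    hit
  }
  first_time_by_subject <- function(hit) {
    if (!any(hit)) return(data.table::data.table(subject_id = character(0), t = numeric(0)))
    rec[hit, list(t = min(time)), by = "subject_id"]
  }

  ids <- unique(rec$subject_id)
  n0 <- length(ids)
  ledger <- c(no_entry_marker = 0L, outcome_before_entry = 0L,
              death_on_or_before_entry = 0L, zero_followup = 0L,
              exclusion_codelist = 0L)

  # entry: earliest entry-marker record across all entry codelists
  entry_hit <- Reduce(`|`, lapply(entry_cl, match_cl))
  entry <- first_time_by_subject(entry_hit)
  data.table::setnames(entry, "t", "entry_time")
  ledger["no_entry_marker"] <- n0 - nrow(entry)

  # first occurrence per outcome component (for attribution) and overall
  priority <- config$outcome_priority %||% vapply(outcome_cl, `[[`, "", "name")
  comp_times <- lapply(outcome_cl, function(cl) {
    ft <- first_time_by_subject(match_cl(cl))
    data.table::setnames(ft, "t", paste0("t_", cl$name))
    ft
  })
  tab <- entry
  for (ct in comp_times) tab <- merge(tab, ct, by = "subject_id", all.x = TRUE)

  death <- first_time_by_subject(rec$channel == "death")
  data.table::setnames(death, "t", "death_time")
  tab <- merge(tab, death, by = "subject_id", all.x = TRUE)

  comp_cols <- paste0("t_", vapply(outcome_cl, `[[`, "", "name"))
  tm <- as.matrix(tab[, comp_cols, with = FALSE])
  outcome_time <- suppressWarnings(apply(tm, 1L, min, na.rm = TRUE))
  outcome_time[!is.finite(outcome_time)] <- NA_real_

  # exclusion codelists: any matching record, any time
  if (length(excl_cl)) {
    excl_hit <- Reduce(`|`, lapply(excl_cl, match_cl))
    excl_ids <- unique(rec$subject_id[excl_hit])
  } else excl_ids <- character(0)

  keep <- rep(TRUE, nrow(tab))
  oy <- outcome_time
  et <- tab$entry_time
  drop_outcome <- !is.na(oy) & oy < et
  ledger["outcome_before_entry"] <- sum(drop_outcome)
  keep <- keep & !drop_outcome
  drop_death <- !is.na(tab$death_time) & tab$death_time <= et
  ledger["death_on_or_before_entry"] <- sum(drop_death & keep)
  keep <- keep & !drop_death
  # entry and outcome on the same day: zero follow-up, excluded
  drop_zero <- !is.na(oy) & oy == et
  ledger["zero_followup"] <- sum(drop_zero & keep)
  keep <- keep & !drop_zero
  drop_excl <- tab$subject_id %in% excl_ids
  ledger["exclusion_codelist"] <- sum(drop_excl & keep)
  keep <- keep & !drop_excl

  tab <- tab[keep]
  oy <- oy[keep]
  end_time <- pmin(ifelse(is.na(oy), Inf, oy),
                   ifelse(is.na(tab$death_time), Inf, tab$death_time),
                   config$study_end)
  event <- as.integer(is.finite(oy) & oy <= end_time)
  # same-day component ties resolved by configured priority order
  comp <- rep(NA_character_, nrow(tab))
  if (any(event == 1)) {
    tmk <- as.matrix(tab[, comp_cols, with = FALSE])
    for (nm in rev(priority)) {
      col <- paste0("t_", nm)
      if (!col %in% comp_cols) next
      hit <- event == 1 & !is.na(tmk[, col]) & tmk[, col] == oy
      comp[hit] <- nm
    }
  }
  followup_years <- (end_time - tab$entry_time) / 365.25
  pos <- followup_years > 0
  ledger["zero_followup"] <- ledger["zero_followup"] + sum(!pos)

  out <- data.frame(subject_id = tab$subject_id[pos],
                    entry_time = tab$entry_time[pos],
                    followup_years = followup_years[pos],
                    event = event[pos],
                    event_component = comp[pos],
                    stringsAsFactors = FALSE)

  # baseline feature extraction
  feats <- config$features %||% list()
  for (v in names(feats)) {
    f <- feats[[v]]
    cl <- codelist(v, f$channel, f$patterns, role = "exposure")
    hit <- match_cl(cl)
    if (identical(f$kind, "numeric")) {
      sub <- rec[hit & !is.na(rec$value)]
      sub <- merge(sub, tab[pos, c("subject_id", "entry_time")], by = "subject_id")
      sub <- sub[sub$time <= sub$entry_time]
      if (nrow(sub)) {
        last <- sub[order(sub$time), list(v = data.table::last(value)), by = "subject_id"]
        out[[v]] <- last$v[match(out$subject_id, last$subject_id)]
      } else out[[v]] <- NA_real_
    } else {
      sub <- rec[hit]
      sub <- merge(sub, tab[pos, c("subject_id", "entry_time")], by = "subject_id")
      sub <- sub[sub$time <= sub$entry_time]
      out[[v]] <- as.numeric(out$subject_id %in% unique(sub$subject_id))
    }
  }
  if (!is.null(config$min_age) && "age" %in% names(out)) {
    young <- !is.na(out$age) & out$age < config$min_age
    ledger <- c(ledger, below_min_age = sum(young))
    out <- out[!young, , drop = FALSE]
  }

  if (is.null(catalog)) {
    if (length(feats)) {
      catalog <- variable_catalog(
        names(feats),
        kind = vapply(feats, function(f) f$kind %||% "binary", ""),
        group = vapply(feats, function(f) f$group %||% "disease_history", "")
      )
    } else {
      catalog <- variable_catalog(character(0))
    }
  }
  ct <- cohort_table(out, catalog)
  attr(ct, "exclusion_ledger") <- ledger
  ct
}

#' @rdname build_cohort
#' @param cohort a `cohort_table` built by `build_cohort`.
#' @export
exclusion_ledger <- function(cohort) attr(cohort, "exclusion_ledger")

#' Kaplan-Meier survival probability at a time point
#'
#' Product-limit estimate with a Greenwood-based confidence interval,
#' evaluated at `t` (right-continuous step function; the estimate at the
#' last observed time is carried forward beyond it).
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (same length).
#' @param t evaluation time, `>= 0`.
#' @param conf_level confidence level for the Greenwood interval.
#' @return list with `surv`, `lower`, `upper`.
#' @export
km_survival <- function(times, events, t, conf_level = 0.95) {
  stopifnot(length(times) == length(events), t >= 0)
  if (t == 0 || length(times) == 0L) return(list(surv = 1, lower = 1, upper = 1))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.int = conf_level, conf.type = "log")
  step_at <- function(y) {
    i <- findInterval(t, fit$time)
    if (i == 0L) 1 else y[i]
  }
  lo <- fit$lower; hi <- fit$upper
  lo[is.na(lo)] <- 0; hi[is.na(hi)] <- 1
  list(surv = step_at(fit$surv),
       lower = if (findInterval(t, fit$time) == 0L) 1 else step_at(lo),
       upper = if (findInterval(t, fit$time) == 0L) 1 else step_at(hi))
}

#' Summarize a cohort (incidence table)
#'
#' Computes the descriptive quantities of a cohort incidence table:
#' subject and event counts, person-years, the event rate per 1000
#' person-years, median follow-up with 5th/95th percentiles, the
#' Kaplan-Meier event rate at the horizon with its confidence interval,
#' and the composition of events by first-event component.
#'
#' @param cohort a `cohort_table`.
#' @param horizon horizon in years for the KM event rate (default 10).
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort, horizon = 10) {
  d <- cohort$data
  if (nrow(d) == 0L) stop("invalid cohort: no subjects")
  py <- sum(d$followup_years)
  if (py <= 0) stop("invalid cohort: zero person-years")
  n_events <- sum(d$event)
  km <- km_survival(d$followup_years, d$event, horizon)
  comp <- NULL
  if ("event_component" %in% names(d) && n_events > 0) {
    cc <- table(d$event_component[d$event == 1])
    comp <- data.frame(component = names(cc), count = as.integer(cc),
                       share = as.integer(cc) / n_events)
  }
  structure(list(
    n = nrow(d),
    n_events = n_events,
    person_years = py,
    event_rate_per_1000py = event_rate_per_1000py(n_events, py),
    median_followup_years = unname(stats::quantile(d$followup_years, 0.5)),
    followup_p5 = unname(stats::quantile(d$followup_years, 0.05)),
    followup_p95 = unname(stats::quantile(d$followup_years, 0.95)),
    km_event_rate = 1 - km$surv,
    km_event_rate_lower = 1 - km$upper,
    km_event_rate_upper = 1 - km$lower,
    horizon = horizon,
    composition = comp
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d, events = %d (%.0f%%)\n", x$n, x$n_events,
              100 * x$n_events / x$n))
  cat(sprintf("person-years = %.0f, event rate = %.1f per 1000 PY\n",
              x$person_years, x$event_rate_per_1000py))
  cat(sprintf("median follow-up = %.1f y (5th-95th: %.1f-%.1f)\n",
              x$median_followup_years, x$followup_p5, x$followup_p95))
  cat(sprintf("%g-year KM event rate = %.1f%% (%.1f-%.1f)\n", x$horizon,
              100 * x$km_event_rate, 100 * x$km_event_rate_lower,
              100 * x$km_event_rate_upper))
  if (!is.null(x$composition)) {
    for (i in seq_len(nrow(x$composition))) {
      cat(sprintf("  %s: %d (%.0f%%)\n", x$composition$component[i],
                  x$composition$count[i], 100 * x$composition$share[i]))
    }
  }
  invisible(x)
}

#' Event rate per 1000 person-years
#'
#' @param n_events number of incident events.
#' @param person_years total person-years at risk.
#' @return events per 1000 person-years (unrounded).
#' @export
event_rate_per_1000py <- function(n_events, person_years) {
  if (any(person_years <= 0)) stop("invalid cohort: zero person-years")
  1000 * n_events / person_years
}

`%||%` <- function(a, b) if (is.null(a)) b else a
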