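#' Variable catalogs and codelists
#'
#' A `variable_catalog` describes every covariate a cohort may carry: its
#' type, clinical group, whether it is one of the mandatory risk predictors
#' that every fitted model must contain, and whether it belongs to the
#' additional set of clinically important fields that are population-mean
#' imputed at prediction time.
#'
#' @param name character vector of unique variable names.
#' @param kind `"numeric"` or `"binary"`, recycled.
#' @param group clinical group, one of `"demographic"`, `"lab"`,
#'   `"disease_history"`, `"medication"`, `"family_history"`,
#'   `"utilization"`; recycled.
#' @param mandatory logical; forced into every fitted model.
#' @param mandatory_imputable logical; numeric fields filled with the
#'   derivation-cohort population mean at prediction time, binary fields
#'   treated as absent-equals-zero.
#' @param units character units label (free text, `""` for none).
#' @return A data frame of class `variable_catalog`.
#' @export
variable_catalog <- function(name, kind = "numeric", group = "lab",
                             mandatory = FALSE, mandatory_imputable = FALSE,
                             units = "") {
  cat <- data.frame(
    name = as.character(name),
    kind = rep_len(as.character(kind), length(name)),
    group = rep_len(as.character(group), length(name)),
    mandatory = rep_len(as.logical(mandatory), length(name)),
    mandatory_imputable = rep_len(as.logical(mandatory_imputable), length(name)),
    units = rep_len(as.character(units), length(name)),
    stringsAsFactors = FALSE
  )
  class(cat) <- c("variable_catalog", "data.frame")
  validate_catalog(cat)
}

#' @rdname variable_catalog
#' @param cat a `variable_catalog`.
#' @export
validate_catalog <- function(cat) {
  stopifnot(is.data.frame(cat))
  if (anyDuplicated(cat$name)) {
    stop("variable names must be unique: ",
         paste(unique(cat$name[duplicated(cat$name)]), collapse = ", "))
  }
  if (!all(cat$kind %in% c("numeric", "binary"))) {
    stop("kind must be 'numeric' or 'binary'")
  }
  groups <- c("demographic", "lab", "disease_history", "medication",
              "family_history", "utilization")
  if (!all(cat$group %in% groups)) {
    stop("unknown variable group: ",
         paste(setdiff(cat$group, groups), collapse = ", "))
  }
  if (any(cat$mandatory & cat$mandatory_imputable)) {
    stop("a variable cannot be both mandatory and mandatory_imputable")
  }
  cat
}

#' @rdname variable_catalog
#' @export
mandatory_vars <- function(cat) cat$name[cat$mandatory]

#' @rdname variable_catalog
#' @export
mandatory_imputable_vars <- function(cat) cat$name[cat$mandatory_imputable]

CHANNELS <- c("lab", "vitals", "diagnosis", "procedure", "dispensing",
              "attendance", "death")

.datatable.aware <- TRUE

#' Create a codelist
#'
#' A codelist names a clinical concept and the code prefixes that define it
#' within one record channel. Codelists drive cohort assembly: entry markers
#' (e.g. the first lipid test), outcome components (e.g. coronary heart
#' disease), exclusions (e.g. congestive heart failure, nitrate dispensing).
#' Code dictionaries themselves (ICD-9-CM, BNF) are user-supplied.
#'
#' @param name unique concept name.
#' @param channel record channel the codes live in; one of
#'   `r paste0('"', CHANNELS, '"', collapse = ", ")`.
#' @param patterns non-empty character vector of code prefixes; a record
#'   matches when its code starts with any prefix.
#' @param role one of `"outcome_component"`, `"exposure"`, `"exclusion"`,
#'   `"entry_marker"`.
#' @return A list of class `codelist`.
#' @export
codelist <- function(name, channel, patterns,
                     role = c("outcome_component", "exposure", "exclusion",
                              "entry_marker")) {
  role <- match.arg(role)
  stopifnot(length(name) == 1L, length(channel) == 1L)
  if (!channel %in% CHANNELS) stop("unknown channel: ", channel)
  if (length(patterns) == 0L) stop("codelist '", name, "' has no patterns")
  structure(list(name = name, channel = channel,
                 patterns = as.character(patterns), role = role),
            class = "codelist")
}

#' Construct a cohort table
#'
#' One row per subject: identifier, follow-up in years, event indicator and
#' the covariates named in the catalog. Missing covariate values are `NA`;
#' the observed/missing mask is therefore implicit in the data.
#'
#' @param data data frame with columns `subject_id`, `followup_years`,
#'   `event`, then one column per catalog variable (extra bookkeeping
#'   columns such as `event_component` are allowed).
#' @param catalog a `variable_catalog` governing the covariate columns.
#' @return A list of class `cohort_table` with elements `data` and `catalog`.
#' @export
cohort_table <- function(data, catalog) {
  validate_catalog(catalog)
  req <- c("subject_id", "followup_years", "event")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("cohort data lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$subject_id)) stop("subject_ids must be unique")
  if (any(!is.finite(data$followup_years)) || any(data$followup_years <= 0)) {
    stop("followup_years must be positive and finite")
  }
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  absent <- setdiff(catalog$name, names(data))
  if (length(absent)) stop("catalog variables missing from data: ",
                           paste(absent, collapse = ", "))
  for (v in catalog$name[catalog$kind == "binary"]) {
    x <- data[[v]]
    if (!all(x[!is.na(x)] %in% c(0, 1))) stop("binary variable '", v, "' must be 0/1")
  }
  structure(list(data = as.data.frame(data), catalog = catalog),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  d <- x$data
  cat(sprintf("<cohort_table> %d subjects, %d events (%.1f%%), %d covariates\n",
              nrow(d), sum(d$event), 100 * mean(d$event), nrow(x$catalog)))
  cat(sprintf("  person-years %.0f, median follow-up %.2f y\n",
              sum(d$followup_years), stats::median(d$followup_years)))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) c(nrow(x$data), nrow(x$catalog))

# covariate matrix for modelling; binary NAs are absent-equals-zero flags
cohort_matrix <- function(cohort, vars, binary_na_zero = TRUE) {
  d <- cohort$data
  cat <- cohort$catalog
  X <- matrix(NA_real_, nrow(d), length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    x <- as.numeric(d[[v]])
    if (binary_na_zero && cat$kind[match(v, cat$name)] == "binary") {
      x[is.na(x)] <- 0
    }
    X[, v] <- x
  }
  X
}
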