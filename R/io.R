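#' Read and write wide cohort tables
#'
#' Wide cohort CSV: header `subject_id,followup_years,event,<var1>,...`,
#' missing values as empty fields; the catalog travels in a YAML or JSON
#' sidecar with per-variable `name`, `kind`, `group`, `mandatory`,
#' `mandatory_imputable`, `units`.
#'
#' @param path cohort CSV path.
#' @param catalog_path catalog sidecar (`.yaml`/`.yml`/`.json`).
#' @return a `cohort_table`.
#' @export
read_cohort_csv <- function(path, catalog_path) {
  cat <- read_catalog(catalog_path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(d, cat)
}

#' @rdname read_cohort_csv
#' @param cohort a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path, catalog_path = NULL) {
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "")
  if (!is.null(catalog_path)) write_catalog(cohort$catalog, catalog_path)
  invisible(path)
}

#' @rdname read_cohort_csv
#' @export
read_catalog <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- raw$variables %||% raw
  variable_catalog(
    name = vapply(vars, `[[`, "", "name"),
    kind = vapply(vars, function(v) v$kind %||% "numeric", ""),
    group = vapply(vars, function(v) v$group %||% "lab", ""),
    mandatory = vapply(vars, function(v) isTRUE(v$mandatory), TRUE),
    mandatory_imputable = vapply(vars, function(v) isTRUE(v$mandatory_imputable), TRUE),
    units = vapply(vars, function(v) v$units %||% "", "")
  )
}

#' @rdname read_cohort_csv
#' @param cat a `variable_catalog`.
#' @export
write_catalog <- function(cat, path) {
  vars <- lapply(seq_len(nrow(cat)), function(i) {
    list(name = cat$name[i], kind = cat$kind[i], group = cat$group[i],
         mandatory = cat$mandatory[i],
         mandatory_imputable = cat$mandatory_imputable[i],
         units = cat$units[i])
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(list(variables = vars), path)
  } else {
    jsonlite::write_json(list(variables = vars), path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read long-format longitudinal records
#'
#' CSV with header `subject_id,time,channel,code,value`; missing value =
#' empty field.
#'
#' @param path CSV path.
#' @return data frame of records.
#' @export
read_records_csv <- function(path) {
  req <- c("subject_id", "time", "channel", "code", "value")
  hdr <- names(utils::read.csv(path, nrows = 0))
  miss <- setdiff(req, hdr)
  if (length(miss)) stop("records CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      time = "numeric", channel = "character",
                                      code = "character", value = "numeric"))
  bad <- setdiff(unique(d$channel), CHANNELS)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  d
}

#' Read codelists and cohort rules from one YAML/JSON config
#'
#' @param path config path. Expected keys: `codelists` (list of name,
#'   channel, patterns, role) and `cohort` (study_end, optional min_age,
#'   outcome_priority, features).
#' @return list with `codelists` (list of [codelist()]) and `config`.
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- lapply(raw$codelists, function(cl) {
    codelist(cl$name, cl$channel, unlist(cl$patterns), cl$role)
  })
  list(codelists = cls, config = raw$cohort %||% list())
}

MODEL_SCHEMA_VERSION <- "1"

#' Serialize / restore a stacked model as JSON
#'
#' Single versioned JSON document holding the ridge coefficients, the
#' Breslow baseline grid, centring constant, imputation means, any
#' recalibration parameters, and (for full models) the boosted ensemble as
#' base64-encoded booster bytes with its hyperparameters.
#'
#' @param model a `stacked_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    flavor = model$flavor,
    coef = as.list(model$coef),
    info = list(names = rownames(model$info),
                values = as.vector(model$info)),
    lambda = model$lambda,
    center = model$center,
    horizon = model$horizon,
    s0 = list(time = model$s0$time, cumhaz = model$s0$cumhaz),
    recal_shift = model$recal_shift %||% 0,
    recal_slope = model$recal_slope %||% 1,
    variables = model$variables,
    imputation = if (!is.null(model$imputation)) {
      list(vars = model$imputation$vars,
           population_means = as.list(model$imputation$population_means),
           m = model$imputation$m, iterations = model$imputation$iterations,
           seed = model$imputation$seed)
    },
    boosted = if (!is.null(model$boosted)) {
      b <- model$boosted
      list(raw_b64 = jsonlite::base64_enc(as.raw(b$raw)),
           variables = b$variables, offset = b$offset,
           hp = unclass(b$hp))
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("unsupported model schema version: ", obj$schema_version)
  }
  p <- length(obj$info$names)
  info <- matrix(obj$info$values, p, p,
                 dimnames = list(obj$info$names, obj$info$names))
  model <- list(
    coef = unlist(obj$coef), info = info, lambda = obj$lambda,
    center = obj$center, horizon = obj$horizon,
    s0 = data.frame(time = obj$s0$time, cumhaz = obj$s0$cumhaz,
                    surv = exp(-obj$s0$cumhaz)),
    flavor = obj$flavor, variables = obj$variables,
    recal_shift = obj$recal_shift, recal_slope = obj$recal_slope,
    imputation = if (!is.null(obj$imputation)) {
      structure(list(vars = obj$imputation$vars,
                     population_means = unlist(obj$imputation$population_means),
                     m = obj$imputation$m,
                     iterations = obj$imputation$iterations,
                     seed = obj$imputation$seed),
                class = "imputation_model")
    },
    boosted = if (!is.null(obj$boosted)) {
      structure(list(raw = jsonlite::base64_dec(obj$boosted$raw_b64),
                     variables = obj$boosted$variables,
                     offset = obj$boosted$offset,
                     hp = structure(as.list(obj$boosted$hp),
                                    class = "boost_hyperparams")),
                class = "boosted_cox_model")
    }
  )
  class(model) <- "stacked_model"
  model
}

#' Reference cohort incidence counts
#'
#' Published incidence-table counts for three Hong Kong territory-wide
#' EHR cohorts (one derivation, two validation): subjects, incident
#' cardiovascular events, person-years, and the first-event composition by
#' outcome component. Shipped so that incidence-rate arithmetic
#' (events per 1000 person-years, component shares) can be recomputed.
#'
#' @return data frame with one row per cohort.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_cohort_counts.csv",
                      package = "coxstack")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
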