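#' Write / read a synthetic cohort as CSV
#'
#' `patients.csv` and `measurements.csv` hold the observable tables (UTF-8,
#' comma-separated, ISO-8601 dates); `truth.csv` (optional) holds the hidden
#' generative truth for recovery experiments.
#'
#' @param cohort an `fbc_cohort`.
#' @param dir output directory (created if needed).
#' @param truth whether to write `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(cohort$measurements, file.path(dir, "measurements.csv"),
            row.names = FALSE)
  if (truth && !is.null(cohort$truth)) {
    write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pat <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  for (col in c("entry_date", "exit_date", "diagnosis_date")) {
    pat[[col]] <- as.Date(pat[[col]])
  }
  mea <- read.csv(file.path(dir, "measurements.csv"), stringsAsFactors = FALSE)
  mea$date <- as.Date(mea$date)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    read.csv(truth_path, stringsAsFactors = FALSE)
  }
  structure(list(patients = pat, measurements = mea, truth = truth,
                 config = NULL), class = "fbc_cohort")
}

#' Write a prepared cohort
#'
#' `prepared_cohort.csv` has one row per retained measurement with its
#' window time plus the patient-level outcome columns; `flow.json` records
#' the exclusion counts of every preparation stage.
#'
#' @param prepared an `fbc_prepared`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_prepared <- function(prepared, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pcols <- c("patient_id", "sex", "age_at_baseline", "baseline_date",
             "event", "followup_years", "n_fbc", "fbc_span_years")
  pcols <- intersect(pcols, names(prepared$patients))
  flat <- merge(prepared$measurements, prepared$patients[, pcols],
                by = "patient_id", sort = FALSE)
  write.csv(flat, file.path(dir, "prepared_cohort.csv"), row.names = FALSE)
  jsonlite::write_json(prepared$flow, file.path(dir, "flow.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_prepared
#' @export
read_prepared <- function(dir) {
  flat <- read.csv(file.path(dir, "prepared_cohort.csv"), stringsAsFactors = FALSE)
  flat$date <- as.Date(flat$date)
  flat$baseline_date <- as.Date(flat$baseline_date)
  mcols <- c("patient_id", "analyte", "value", "date", "window_time")
  pcols <- setdiff(names(flat), setdiff(mcols, "patient_id"))
  patients <- unique(flat[, pcols])
  rownames(patients) <- NULL
  flow <- jsonlite::read_json(file.path(dir, "flow.json"), simplifyVector = TRUE)
  structure(list(patients = patients, measurements = flat[, mcols], flow = flow),
            class = "fbc_prepared")
}


#' Serialise / deserialise a fitted model bundle
#'
#' One JSON file carrying the three longitudinal sub-models (named
#' coefficient arrays, knots, covariance entries, residual variance, fit
#' metadata), the Cox sub-model (coefficients, SEs, covariate means, Breslow
#' baseline survival, age scaling) and run metadata. Numbers are written at
#' full precision so re-reading the bundle reproduces predictions exactly.
#'
#' @param bundle an `fbc_joint_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_bundle <- function(bundle, path) {
  long <- lapply(bundle$longitudinal, function(p) {
    list(analyte = p$analyte, beta = as.list(p$beta),
         G = list(intercept_var = p$G[1, 1], covariance = p$G[1, 2],
                  slope_var = p$G[2, 2]),
         sigma2 = p$sigma2,
         spec = list(age_knots = p$spec$age_knots,
                     time_knots = p$spec$time_knots,
                     age_time_interaction = p$spec$age_time_interaction),
         n_obs = p$n_obs, n_patients = p$n_patients,
         logLik = p$logLik, converged = p$converged)
  })
  cox <- bundle$cox
  obj <- list(
    format = "fbctrend-bundle", version = 1L,
    longitudinal = long,
    cox = list(coef = as.list(cox$coef), se = as.list(cox$se),
               covariate_means = as.list(cox$covariate_means),
               s0_2y = cox$s0_2y, age_scale = cox$age_scale,
               horizon = cox$horizon, n = cox$n, n_events = cox$n_events),
    meta = bundle$meta
  )
  # digits = I(17): doubles round-trip exactly, so a re-read bundle
  # reproduces predictions bit for bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "fbctrend-bundle")) {
    stop("not a fbctrend model bundle: ", path)
  }
  num <- function(x) vapply(x, as.numeric, numeric(1))
  long <- lapply(obj$longitudinal, function(p) {
    G <- matrix(c(p$G$intercept_var, p$G$covariance,
                  p$G$covariance, p$G$slope_var), 2, 2)
    longit_params(p$analyte, beta = num(p$beta), G = G, sigma2 = p$sigma2,
                  spec = list(analyte = p$analyte,
                              age_knots = num(p$spec$age_knots),
                              time_knots = num(p$spec$time_knots),
                              age_time_interaction = isTRUE(p$spec$age_time_interaction)),
                  n_obs = p$n_obs %||% NA_integer_,
                  n_patients = p$n_patients %||% NA_integer_,
                  logLik = p$logLik %||% NA_real_,
                  converged = p$converged %||% NA)
  })
  names(long) <- vapply(long, `[[`, character(1), "analyte")
  cx <- obj$cox
  se <- vapply(cx$se, function(z) if (is.null(z)) NA_real_ else as.numeric(z),
               numeric(1))
  names(se) <- names(cx$se)
  coefs <- num(cx$coef)
  cox <- structure(list(
    coef = coefs, se = se,
    hr_ci = cbind(hr = exp(coefs), lower = exp(coefs - 1.96 * se),
                  upper = exp(coefs + 1.96 * se)),
    covariate_means = num(cx$covariate_means), s0_2y = cx$s0_2y,
    age_scale = cx$age_scale, horizon = cx$horizon, n = cx$n,
    n_events = cx$n_events), class = "fbc_cox_params")
  structure(list(longitudinal = long, cox = cox, development = NULL,
                 meta = obj$meta), class = "fbc_joint_model")
}

#' Write a performance report (or list of reports) as JSON
#'
#' @param report `fbc_performance` or a named list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_performance <- function(report, path) {
  flatten <- function(r) {
    list(label = r$label, n = r$n, n_events = r$n_events, brier = r$brier,
         c_statistic = r$c_statistic, d_statistic = r$d_statistic,
         r2_d = r$r2_d, calibration_slope = r$calibration_slope,
         calibration_bins = r$calibration_bins, wide_ci = r$wide_ci)
  }
  obj <- if (inherits(report, "fbc_performance")) flatten(report)
         else lapply(report, flatten)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Default run configuration
#'
#' The settings of the standard workflow: spline knots (age 60/70/80 for
#' haemoglobin, 55 for MCV, 60 for platelets; time knot at year 3), the
#' five-year longitudinal window, 21-month exclusion window, 27-month
#' outcome window, two-year horizon, percentiles 75-99, unit FP age scaling.
#'
#' @param sex cohort sex.
#' @param seed integer seed.
#' @return nested list; serialisable to YAML with [write_run_config()].
#' @export
default_run_config <- function(sex = "male", seed = 1L) {
  list(
    sex = sex, seed = as.integer(seed),
    window_years = 5, exclusion_window_months = 21,
    outcome_window_months = 27, horizon_years = 2,
    min_age = 40, min_registration_years = 1,
    age_scale = 1,
    plausible_ranges = plausible_ranges_default(),
    spline_knots = list(HB = c(60, 70, 80), MCV = 55, PLT = 60, time = 3),
    percentiles = c(75, 80, 85, 90, 95, 99),
    n_patients = 20000, event_rate_multiplier = 1
  )
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(sex = cfg$sex %||% "male", seed = cfg$seed %||% 1L)
  utils::modifyList(base, cfg)
}

#' @rdname default_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
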