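#' Fit the Cox sub-model
#'
#' Maximises the Cox partial likelihood (Breslow tie handling) over the five
#' covariates of the survival sub-model: the two fractional-polynomial age
#' terms and the three trend-deviation covariates, kept in analyte units so
#' hazard ratios are per g/dL (haemoglobin), per fL (MCV) and per platelet
#' unit. Covariate means are stored for mean-centred prediction and the
#' Breslow baseline survival at `horizon` years is computed from the fit.
#'
#' Covariates that are constant in the data carry no information; their
#' coefficients are fixed at zero (with a warning) rather than dropped, so
#' the parameter vector keeps its five named slots.
#'
#' @param followup_years,event follow-up time (years) and event indicator.
#' @param age age at baseline, years.
#' @param deviations data frame with columns `d_hb`, `d_mcv`, `d_plt`.
#' @param age_scale divisor applied to age before the FP transform.
#' @param horizon horizon (years) for the Breslow baseline survival.
#' @return object of class `fbc_cox_params`: named coefficients (log HR),
#'   `se`, `hr_ci` (HR with 95% CI), `covariate_means`, `s0_2y`, `age_scale`,
#'   `horizon`, `n`, `n_events`.
#' @export
fit_cox <- function(followup_years, event, age, deviations, age_scale = 1,
                    horizon = 2) {
  if (sum(event) < 2) stop("Cox sub-model requires at least 2 events")
  fp <- fp_age_terms(age, age_scale)
  X <- cbind(age2 = fp[, "age2"], age2log = fp[, "age2log"],
             d_hb = deviations$d_hb, d_mcv = deviations$d_mcv,
             d_plt = deviations$d_plt)
  if (any(!is.finite(X))) stop("non-finite covariate values in Cox sub-model")

  keep <- apply(X, 2, function(z) sd(z) > 0)
  coefs <- setNames(numeric(ncol(X)), colnames(X))
  ses <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  if (!all(keep)) {
    warning("constant covariate(s) in Cox sub-model fixed at zero: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  if (any(keep)) {
    dat <- data.frame(time = followup_years, event = event, X[, keep, drop = FALSE])
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(colnames(X)[keep], collapse = " + ")))
    fit <- survival::coxph(fml, data = dat, ties = "breslow")
    coefs[names(coef(fit))] <- coef(fit)
    ses[names(coef(fit))] <- sqrt(diag(vcov(fit)))
  }

  means <- colMeans(X)
  lp_c <- drop(X %*% coefs) - sum(means * coefs)
  s0 <- breslow_baseline_survival(followup_years, event, lp_c, horizon)

  hr_ci <- cbind(hr = exp(coefs),
                 lower = exp(coefs - 1.96 * ses),
                 upper = exp(coefs + 1.96 * ses))
  structure(list(coef = coefs, se = ses, hr_ci = hr_ci,
                 covariate_means = means, s0_2y = s0, age_scale = age_scale,
                 horizon = horizon, n = length(event), n_events = sum(event)),
            class = "fbc_cox_params")
}

#' Breslow baseline survival
#'
#' Baseline survivor probability at `horizon` for mean-centred predictors:
#' `S0(t) = exp(-H0(t))` with the Breslow cumulative hazard
#' `H0(t) = sum over event times tj <= t of d_j / sum(risk set at tj) exp(lp)`.
#' With all linear predictors zero this is `exp(-)` of the Nelson-Aalen
#' estimator.
#'
#' @param followup_years,event follow-up times and event indicators.
#' @param lp_centred mean-centred linear predictors.
#' @param horizon evaluation time in years; if beyond the last follow-up the
#'   estimate at the last event time is returned with a warning.
#' @return survivor probability in (0, 1\].
#' @export
breslow_baseline_survival <- function(followup_years, event, lp_centred,
                                      horizon = 2) {
  if (horizon > max(followup_years)) {
    warning("horizon beyond last follow-up time; returning the estimate at ",
            "the last observed event time")
  }
  et <- sort(unique(followup_years[event == 1 & followup_years <= horizon]))
  if (!length(et)) return(1.0)
  w <- exp(lp_centred)
  # risk-set sums of exp(lp) at each event time, via reverse cumulative sums
  ord <- order(followup_years)
  t_s <- followup_years[ord]
  w_s <- w[ord]
  rev_cum <- rev(cumsum(rev(w_s)))  # sum of w over t >= t_s[i]
  # for each event time, first index with t_s >= et
  pos <- findInterval(et, t_s, left.open = TRUE) + 1L
  s0_at <- rev_cum[pos]
  d <- vapply(et, function(tt) sum(event == 1 & followup_years == tt), numeric(1))
  H0 <- sum(d / s0_at)
  exp(-H0)
}

#' Absolute two-year risk from fitted parameters
#'
#' `risk = 1 - s0^exp(lp)` with the mean-centred linear predictor
#' `lp = gamma . FP(age) + sum alpha_k d_k - centring`.
#'
#' @param params `fbc_cox_params` fit (or a compatible list).
#' @param age age at baseline, years.
#' @param deviations data frame with `d_hb`, `d_mcv`, `d_plt` (analyte units).
#' @return data frame with `linear_predictor` and `risk_2y`.
#' @export
two_year_risk <- function(params, age, deviations) {
  fp <- fp_age_terms(age, params$age_scale)
  X <- cbind(age2 = fp[, "age2"], age2log = fp[, "age2log"],
             d_hb = deviations$d_hb, d_mcv = deviations$d_mcv,
             d_plt = deviations$d_plt)
  lp <- as.vector(X %*% params$coef) - sum(params$covariate_means * params$coef)
  data.frame(linear_predictor = lp, risk_2y = 1 - params$s0_2y^exp(lp))
}

# BLUP trend deviations of every patient in a prepared cohort, using the
# bundle's longitudinal parameters.
cohort_deviations <- function(longitudinal, prepared, t_baseline = 5) {
  devs <- lapply(names(FBC_ANALYTES), function(a) {
    re <- estimate_random_effects_all(longitudinal[[a]], prepared)
    trend_deviation(re, t_baseline)
  })
  names(devs) <- tolower(paste0("d_", names(FBC_ANALYTES)))
  out <- data.frame(patient_id = prepared$patients$patient_id,
                    stringsAsFactors = FALSE)
  for (nm in names(devs)) out[[nm]] <- devs[[nm]]
  out
}

#' Fit the full two-stage joint pipeline
#'
#' Orchestrates the joint model on a prepared single-sex cohort: fits the
#' three per-analyte mixed-effects sub-models, extracts BLUP trend deviations
#' at the baseline time, fits the Cox sub-model on fractional-polynomial age
#' plus the deviations, and computes the Breslow baseline survival at the
#' horizon. The result is a serialisable model bundle.
#'
#' Estimation is two-stage (longitudinal sub-models first, survival
#' sub-model on their BLUPs) rather than a simultaneous maximisation over
#' all six random effects; see the methods vignette for the rationale.
#'
#' @param prepared a [prepare_cohort()] result.
#' @param age_scale FP age scaling (see [fp_age_terms()]).
#' @param horizon risk horizon in years (2).
#' @return object of class `fbc_joint_model`: `longitudinal` (3 fits), `cox`
#'   ([fit_cox()] result), `development` (per-patient deviations, linear
#'   predictor and risk on the development cohort), `meta`.
#' @export
fit_joint_pipeline <- function(prepared, age_scale = 1, horizon = 2) {
  stopifnot(inherits(prepared, "fbc_prepared"))
  longitudinal <- lapply(names(FBC_ANALYTES), function(a) {
    tryCatch(fit_mixed_model(prepared, a),
             error = function(e) stop("longitudinal stage [", a, "]: ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(longitudinal) <- names(FBC_ANALYTES)

  dev <- cohort_deviations(longitudinal, prepared)
  p <- prepared$patients
  cox <- tryCatch(
    fit_cox(p$followup_years, p$event, p$age_at_baseline, dev,
            age_scale = age_scale, horizon = horizon),
    error = function(e) stop("survival stage: ", conditionMessage(e), call. = FALSE))

  pred <- two_year_risk(cox, p$age_at_baseline, dev)
  development <- cbind(dev, pred)

  structure(list(
    longitudinal = longitudinal, cox = cox, development = development,
    meta = list(sex = if ("sex" %in% names(p)) unique(p$sex) else NA_character_,
                n = nrow(p), n_events = sum(p$event),
                horizon = horizon, t_baseline = 5)
  ), class = "fbc_joint_model")
}

#' Dynamic per-patient risk prediction
#'
#' Computes the current two-year risk for one patient from their raw FBC
#' history: the newest measurement date is taken as baseline (time 5), the
#' five-year window is re-anchored there, BLUPs and trend deviations are
#' computed from the bundle's longitudinal parameters, and the Cox
#' sub-model converts them to absolute risk. Calling again after a new FBC
#' arrives yields the updated (dynamic) risk.
#'
#' @param bundle fitted [fit_joint_pipeline()] bundle.
#' @param measurements data frame with `analyte`, `value`, `date` for one
#'   patient; at least one measurement of at least one analyte.
#' @param age age in years at the newest measurement date.
#' @return one-row data frame: `linear_predictor`, `risk_2y`, plus the three
#'   deviations.
#' @export
predict_patient <- function(bundle, measurements, age) {
  if (!nrow(measurements)) stop("empty measurement history")
  baseline <- max(measurements$date)
  wt <- 5 - as.numeric(baseline - measurements$date) / DAYS_PER_YEAR
  keep <- wt >= 0
  measurements <- measurements[keep, , drop = FALSE]
  wt <- wt[keep]
  dev <- lapply(names(FBC_ANALYTES), function(a) {
    i <- measurements$analyte == a
    re <- if (any(i)) {
      estimate_random_effects(bundle$longitudinal[[a]], wt[i],
                              measurements$value[i], age)
    } else {
      warning("no ", a, " measurements in window; population-mean fallback")
      c(b0 = 0, b1 = 0)
    }
    trend_deviation(re, bundle$meta$t_baseline)
  })
  names(dev) <- tolower(paste0("d_", names(FBC_ANALYTES)))
  dev <- as.data.frame(dev)
  cbind(two_year_risk(bundle$cox, age, dev), dev)
}

#' Predict two-year risk for every patient of a prepared cohort
#'
#' @param bundle fitted [fit_joint_pipeline()] bundle.
#' @param prepared a [prepare_cohort()] result (e.g. a validation cohort).
#' @return data frame: `patient_id`, deviations, `linear_predictor`,
#'   `risk_2y`.
#' @export
predict_cohort <- function(bundle, prepared) {
  dev <- cohort_deviations(bundle$longitudinal, prepared, bundle$meta$t_baseline)
  cbind(dev, two_year_risk(bundle$cox, prepared$patients$age_at_baseline, dev))
}

#' @export
print.fbc_cox_params <- function(x, ...) {
  cat(sprintf("Cox sub-model: %d patients, %d events; baseline %g-year survival %.7f\n",
              x$n, x$n_events, x$horizon, x$s0_2y))
  print(round(x$hr_ci, 4))
  invisible(x)
}

#' @export
print.fbc_joint_model <- function(x, ...) {
  cat(sprintf("Joint FBC-trend risk model (%s): n = %d, events = %d\n",
              x$meta$sex, x$meta$n, x$meta$n_events))
  for (a in names(x$longitudinal)) print(x$longitudinal[[a]])
  print(x$cox)
  invisible(x)
}
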