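#' Default longitudinal generative parameters
#'
#' Population trajectory, random-effects covariance and residual variance for
#' each analyte, used as the generative truth of the synthetic cohort
#' generator. Values are chosen to resemble adult primary-care haematology:
#' haemoglobin declining slowly with age (faster beyond the spline knots),
#' MCV rising slightly, platelets falling in men and higher overall in women.
#' They are configuration, not published estimates.
#'
#' @param sex `"male"` or `"female"`.
#' @return named list of three [longit_params()] objects (`HB`, `MCV`, `PLT`).
#' @export
default_longitudinal_truth <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  hb_int <- if (sex == "male") 16.2 else 14.6
  plt_int <- if (sex == "male") 270 else 300
  mcv_int <- if (sex == "male") 87.5 else 88.0
  list(
    HB = longit_params(
      analyte = "HB",
      beta = c(`(Intercept)` = hb_int, age = -0.012, age_k60 = -0.010,
               age_k70 = -0.012, age_k80 = -0.020, time = -0.015,
               time_k3 = -0.010, age_time = -0.0004),
      G = re_cov(sd_intercept = 0.9, sd_slope = 0.15, corr = -0.1),
      sigma2 = 0.7^2
    ),
    MCV = longit_params(
      analyte = "MCV",
      beta = c(`(Intercept)` = mcv_int, age = 0.06, age_k55 = -0.03,
               time = 0.05, time_k3 = 0.00),
      G = re_cov(sd_intercept = 3.5, sd_slope = 0.35, corr = 0.1),
      sigma2 = 2.5^2
    ),
    PLT = longit_params(
      analyte = "PLT",
      beta = c(`(Intercept)` = plt_int, age = -0.4, age_k60 = 0.2,
               time = -1.0, time_k3 = 0.5),
      G = re_cov(sd_intercept = 50, sd_slope = 5.5, corr = -0.2),
      sigma2 = 30^2
    )
  )
}

#' Default survival generative parameters
#'
#' Log hazard ratios of the Cox sub-model used as generative truth: the
#' published sex-specific hazard ratios for the fractional-polynomial age
#' terms and the three trend-deviation covariates, with `age_scale = 1`
#' (coefficients per squared year of age). `baseline_rate` is the constant
#' baseline hazard (per year, at the cohort-mean linear predictor) calibrated
#' so that a default configuration yields a marginal two-year event rate of
#' roughly 0.4% (males) and 0.3% (females).
#'
#' @param sex `"male"` or `"female"`.
#' @return list with elements `gamma_age2`, `gamma_age2log`, `alpha_hb`,
#'   `alpha_mcv`, `alpha_plt` (log hazard ratios), `age_scale`, and
#'   `baseline_rate` (events per year).
#' @export
default_cox_truth <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    list(
      gamma_age2 = log(1.015), gamma_age2log = log(0.997),
      alpha_hb = log(0.868), alpha_mcv = log(0.996), alpha_plt = log(1.001),
      age_scale = 1, baseline_rate = 1.07e-3
    )
  } else {
    list(
      gamma_age2 = log(1.014), gamma_age2log = log(0.997),
      alpha_hb = log(0.863), alpha_mcv = log(0.986), alpha_plt = log(1.002),
      age_scale = 1, baseline_rate = 1.33e-3
    )
  }
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic EHR cohort generator. Defaults encode
#' the study conditions the package is designed around: ages drawn from a
#' truncated normal matching the published cohort age moments, on average 3.2
#' FBC panels per patient over the five-year window (the published
#' measurement-to-patient ratio), the published Cox coefficients as
#' generative truth, and a baseline hazard giving a ~0.3-0.4% marginal
#' two-year event rate at `event_rate_multiplier = 1`.
#'
#' @param n_patients number of patients to generate.
#' @param sex `"male"` or `"female"`; cohorts are single-sex because the
#'   models are sex-stratified.
#' @param seed integer seed; fixing it makes the generated cohort
#'   bit-identical across calls.
#' @param age_distribution list with `mean`, `sd`, `min`, `max` (years); ages
#'   are drawn from the corresponding truncated normal and rounded to whole
#'   years.
#' @param visit_process list with `mean_panels`, the mean number of FBC
#'   panels per patient over the five-year window (one panel = one HB + one
#'   MCV + one PLT measurement); per-patient counts are `1 + Poisson(mean - 1)`
#'   so the baseline panel always exists, with the non-baseline panel times
#'   uniform on the window.
#' @param longitudinal_truth per-analyte [longit_params()] list.
#' @param cox_truth list as returned by [default_cox_truth()].
#' @param event_rate_multiplier positive scalar applied to the baseline
#'   hazard (use e.g. 10 for parameter-recovery experiments where the
#'   realistic event rate gives too few events at desk scale; covariate
#'   hazard ratios are unaffected by baseline-rate scaling).
#' @param censoring list with `exit_rate` (per-year rate of random exit from
#'   the practice within the follow-up window) and `admin_years`
#'   (administrative end of records after baseline, years).
#' @param decoys list with `recent_fraction` (patients given an extra FBC
#'   panel inside the pre-outcome exclusion window, which cohort preparation
#'   must strip), `prewindow_fraction` (patients given a panel older than the
#'   five-year window) and `implausible_rate` (per-row rate of duplicated
#'   rows carrying a biologically impossible value).
#' @return object of class `fbc_sim_config`.
#' @export
simulation_config <- function(n_patients,
                              sex = c("male", "female"),
                              seed = 1L,
                              age_distribution = NULL,
                              visit_process = list(mean_panels = 3.2),
                              longitudinal_truth = NULL,
                              cox_truth = NULL,
                              event_rate_multiplier = 1,
                              censoring = list(exit_rate = 0.4, admin_years = 2.4),
                              decoys = list(recent_fraction = 0.25,
                                            prewindow_fraction = 0.15,
                                            implausible_rate = 0.002)) {
  sex <- match.arg(sex)
  if (!is.numeric(n_patients) || n_patients < 1) stop("n_patients must be >= 1")
  if (event_rate_multiplier <= 0) stop("event_rate_multiplier must be positive")
  if (is.null(age_distribution)) {
    # Published cohort age moments (non-diagnosed patients dominate).
    age_distribution <- if (sex == "male") {
      list(mean = 60.7, sd = 13.0, min = 40, max = 104)
    } else {
      list(mean = 61.9, sd = 14.6, min = 40, max = 108)
    }
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    sex = sex,
    seed = as.integer(seed),
    age_distribution = age_distribution,
    visit_process = visit_process,
    longitudinal_truth = longitudinal_truth %||% default_longitudinal_truth(sex),
    cox_truth = cox_truth %||% default_cox_truth(sex),
    event_rate_multiplier = event_rate_multiplier,
    censoring = censoring,
    decoys = decoys
  )
  class(cfg) <- "fbc_sim_config"
  cfg
}

#' Inverse-transform event-time sampling under a constant baseline hazard
#'
#' Draws an event time from the exponential survival model
#' `S(t) = exp(-rate * exp(lp) * t)` by inverting a uniform draw:
#' `t = -log(u) / (rate * exp(lp))`. Monotone decreasing in `lp` for fixed
#' `u`; doubling the hazard halves the time.
#'
#' @param linear_predictor log relative hazard (centred scale).
#' @param baseline_rate constant baseline hazard, events per year; positive.
#' @param uniform_draw values strictly inside (0, 1).
#' @return event times in years.
#' @export
sample_event_time <- function(linear_predictor, baseline_rate, uniform_draw) {
  if (any(baseline_rate <= 0)) stop("baseline_rate must be positive")
  if (any(uniform_draw <= 0 | uniform_draw >= 1)) {
    stop("uniform_draw must lie strictly inside (0, 1)")
  }
  -log(uniform_draw) / (baseline_rate * exp(linear_predictor))
}

# Draw from N(0, G) via eigendecomposition; tolerates singular (e.g. zero)
# covariances and rejects indefinite ones with a diagnostic naming the analyte.
draw_random_effects <- function(n, G, analyte) {
  e <- eigen(G, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values), 1))) {
    stop(sprintf("random-effects covariance for analyte %s is not positive semi-definite",
                 analyte))
  }
  z <- matrix(rnorm(2 * n), ncol = 2)
  b <- z %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
  colnames(b) <- c("b0", "b1")
  b
}

#' Generate a synthetic EHR cohort
#'
#' Generates a single-sex cohort in which the joint model is the generative
#' mechanism: per-patient random intercepts and slopes for each analyte are
#' drawn from the configured covariances, FBC panel values are the population
#' trajectory plus patient deviation plus residual noise, and the event time
#' is drawn from the Cox sub-model hazard whose covariates are the true trend
#' deviations at the baseline time (time 5) plus fractional-polynomial age.
#'
#' Event times are drawn over the two-year prediction horizon from the
#' constant baseline hazard, and realised diagnosis dates are mapped
#' monotonically into the 21-24-month window after baseline, mirroring the
#' study design in which no patient is diagnosed or censored within two years
#' (minus three months) of baseline; a monotone time transform preserves the
#' proportional-hazards structure, so the configured log hazard ratios remain
#' the estimand of the downstream fit. Non-cases exit at the earliest of a
#' random practice-exit time and the administrative end of records. Decoy
#' measurements (recent panels inside the exclusion window, panels older than
#' the five-year window, duplicated implausible values) exercise the cohort
#' preparation rules without disturbing the generative truth.
#'
#' @param config an [simulation_config()] object.
#' @return object of class `fbc_cohort`: list with `patients`,
#'   `measurements`, `truth` data frames and the `config`. `truth` holds the
#'   hidden per-patient random effects, trend deviations and linear
#'   predictors for recovery tests and is not an observable table.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fbc_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ad <- config$age_distribution
  truth_long <- config$longitudinal_truth
  ct <- config$cox_truth

  # ages: truncated normal, whole years
  age <- numeric(0)
  while (length(age) < n) {
    a <- round(rnorm(2 * (n - length(age)) + 10, ad$mean, ad$sd))
    age <- c(age, a[a >= ad$min & a <= ad$max])
  }
  age <- age[seq_len(n)]

  patient_id <- sprintf("P%07d", seq_len(n))
  baseline_date <- as.Date("2008-06-30") + round(runif(n, -900, 900))
  birth_year <- as.integer(format(baseline_date, "%Y")) - age
  entry_date <- baseline_date - round(5 * DAYS_PER_YEAR + runif(n, 1, 3) * DAYS_PER_YEAR)

  # random effects and true trend deviations at the baseline time (t = 5)
  b <- lapply(names(FBC_ANALYTES), function(a) {
    draw_random_effects(n, truth_long[[a]]$G, a)
  })
  names(b) <- names(FBC_ANALYTES)
  dev <- vapply(names(FBC_ANALYTES), function(a) b[[a]][, "b0"] + 5 * b[[a]][, "b1"],
                numeric(n))

  fp <- fp_age_terms(age, ct$age_scale)
  lp <- ct$gamma_age2 * fp[, "age2"] + ct$gamma_age2log * fp[, "age2log"] +
    ct$alpha_hb * dev[, "HB"] + ct$alpha_mcv * dev[, "MCV"] + ct$alpha_plt * dev[, "PLT"]
  lp_c <- lp - mean(lp)

  u <- runif(n)
  rate <- ct$baseline_rate * config$event_rate_multiplier
  t_raw <- sample_event_time(lp_c, rate, u)
  case <- t_raw <= 2

  # Cases: diagnosis mapped monotonically into (21, 24] months post-baseline
  # (within the study's "two years +/- three months" window), so every event
  # time still has the administratively censored non-cases in its risk set --
  # events later than the censoring horizon would face case-only risk sets,
  # a right-truncation that biases hazard ratios toward the null. The small
  # offset above 21 months guards against day-rounding pushing the baseline
  # FBC inside the exclusion window.
  diag_time <- ifelse(case, 1.755 + 0.1225 * t_raw, NA_real_)
  exit_rand <- 1.755 + rexp(n, rate = config$censoring$exit_rate)
  exit_time <- ifelse(case, diag_time, pmin(exit_rand, config$censoring$admin_years))
  exit_reason <- ifelse(case, "diagnosis",
                        ifelse(exit_rand < config$censoring$admin_years,
                               "left_practice", "end_of_records"))
  exit_date <- baseline_date + round(exit_time * DAYS_PER_YEAR)
  diagnosis_date <- as.Date(ifelse(case, exit_date, NA), origin = "1970-01-01")

  patients <- data.frame(
    patient_id = patient_id, sex = config$sex, birth_year = birth_year,
    age_at_baseline = age, entry_date = entry_date, exit_date = exit_date,
    exit_reason = exit_reason, diagnosis_date = diagnosis_date,
    stringsAsFactors = FALSE
  )

  # FBC panels: baseline panel at t = 5 plus uniform historical panels
  n_panels <- 1L + rpois(n, max(config$visit_process$mean_panels - 1, 0))
  idx <- rep(seq_len(n), n_panels)
  t_panel <- runif(length(idx), 0, 5)
  t_panel[cumsum(n_panels) - n_panels + 1L] <- 5  # first panel per patient = baseline
  panel_date <- baseline_date[idx] - round((5 - t_panel) * DAYS_PER_YEAR)

  measurements <- do.call(rbind, lapply(names(FBC_ANALYTES), function(a) {
    p <- truth_long[[a]]
    mu <- population_trajectory(p, age[idx], t_panel)
    val <- mu + b[[a]][idx, "b0"] + b[[a]][idx, "b1"] * t_panel +
      rnorm(length(idx), 0, sqrt(p$sigma2))
    data.frame(patient_id = patient_id[idx], analyte = a, value = val,
               date = panel_date, stringsAsFactors = FALSE)
  }))

  measurements <- rbind(
    measurements,
    decoy_panels(config, patient_id, age, baseline_date, exit_date, b, truth_long),
    implausible_rows(config, measurements)
  )
  measurements <- measurements[order(measurements$patient_id, measurements$date,
                                     measurements$analyte), ]
  rownames(measurements) <- NULL

  truth <- data.frame(
    patient_id = patient_id,
    b0_hb = b$HB[, "b0"], b1_hb = b$HB[, "b1"],
    b0_mcv = b$MCV[, "b0"], b1_mcv = b$MCV[, "b1"],
    b0_plt = b$PLT[, "b0"], b1_plt = b$PLT[, "b1"],
    d_hb = dev[, "HB"], d_mcv = dev[, "MCV"], d_plt = dev[, "PLT"],
    lp = lp, lp_centred = lp_c, event_time_raw = t_raw, case = case,
    stringsAsFactors = FALSE
  )

  structure(list(patients = patients, measurements = measurements,
                 truth = truth, config = config),
            class = "fbc_cohort")
}

# Extra FBC panels that the preparation stage must remove: panels inside the
# 21-month pre-outcome exclusion window and panels older than the five-year
# longitudinal window. Values continue the patient's own trajectory.
decoy_panels <- function(config, patient_id, age, baseline_date, exit_date,
                         b, truth_long) {
  n <- length(patient_id)
  out <- list()

  sel <- which(runif(n) < config$decoys$recent_fraction)
  if (length(sel)) {
    d_date <- exit_date[sel] - round(runif(length(sel), 0.05, 0.95) * 21 * DAYS_PER_MONTH)
    t_dec <- 5 + as.numeric(d_date - baseline_date[sel]) / DAYS_PER_YEAR
    out$recent <- decoy_values(sel, t_dec, d_date, patient_id, age, b, truth_long)
  }

  sel2 <- which(runif(n) < config$decoys$prewindow_fraction)
  if (length(sel2)) {
    t_dec <- -runif(length(sel2), 0.05, 2)
    d_date <- baseline_date[sel2] - round((5 - t_dec) * DAYS_PER_YEAR)
    out$old <- decoy_values(sel2, t_dec, d_date, patient_id, age, b, truth_long)
  }

  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

decoy_values <- function(sel, t_dec, d_date, patient_id, age, b, truth_long) {
  do.call(rbind, lapply(names(FBC_ANALYTES), function(a) {
    p <- truth_long[[a]]
    mu <- population_trajectory(p, age[sel], t_dec)
    val <- mu + b[[a]][sel, "b0"] + b[[a]][sel, "b1"] * t_dec +
      rnorm(length(sel), 0, sqrt(p$sigma2))
    data.frame(patient_id = patient_id[sel], analyte = a, value = val,
               date = d_date, stringsAsFactors = FALSE)
  }))
}

# Duplicated rows carrying impossible values (e.g. negative), to exercise
# plausible-range filtering without shifting any patient's baseline.
implausible_rows <- function(config, measurements) {
  k <- which(runif(nrow(measurements)) < config$decoys$implausible_rate)
  if (!length(k)) return(NULL)
  bad <- measurements[k, ]
  bad$value <- -abs(bad$value) - 1
  bad
}

#' @export
print.fbc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic FBC cohort: %d %s patients, %d measurements, %d cases (%.2f%%)\n",
              nrow(x$patients), x$config$sex, nrow(x$measurements),
              sum(x$truth$case), 100 * mean(x$truth$case)))
  invisible(x)
}
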