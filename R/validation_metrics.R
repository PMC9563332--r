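# Evaluate a Kaplan-Meier fit at time t (right-continuous step function);
# left = TRUE gives the left limit S(t-).
km_eval <- function(times, surv, t, left = FALSE) {
  idx <- if (left) findInterval(t, times, left.open = TRUE)
         else findInterval(t, times)
  c(1, surv)[idx + 1L]
}

#' Harrell's concordance for censored two-year risk predictions
#'
#' Proportion of usable pairs (an event paired with a patient surviving or
#' censored later) in which the higher predicted risk belongs to the patient
#' with the earlier event; tied predictions score 0.5. Computed through
#' [survival::concordance()] with an asymptotic standard error.
#'
#' @param risk predicted risks (or any monotone score).
#' @param time,event follow-up years and event indicator.
#' @return list `c`, `se`, `ci` (95%).
#' @export
concordance_index <- function(risk, time, event) {
  fit <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)
  if (fit$count[["concordant"]] + fit$count[["discordant"]] +
      fit$count[["tied.x"]] == 0) {
    stop("no comparable pairs for concordance")
  }
  se <- sqrt(fit$var)
  list(c = unname(fit$concordance), se = se,
       ci = unname(fit$concordance) + c(-1.96, 1.96) * se)
}

#' IPCW Brier score at the two-year horizon
#'
#' Mean squared difference between the event indicator at `horizon` and the
#' predicted risk, reweighted by the inverse probability of remaining
#' uncensored (Kaplan-Meier estimate of the censoring distribution), so the
#' score is unbiased under right-censoring. With no censoring before the
#' horizon it reduces to the plain mean squared error.
#'
#' @param risk predicted risks at the horizon.
#' @param time,event follow-up years and event indicator.
#' @param horizon evaluation time, years (2).
#' @return non-negative scalar.
#' @export
brier_two_year <- function(risk, time, event, horizon = 2) {
  cens <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gt <- function(t, left = FALSE) km_eval(cens$time, cens$surv, t, left)
  w <- numeric(length(time))
  is_event <- event == 1 & time <= horizon
  beyond <- time > horizon
  w[is_event] <- 1 / Gt(time[is_event], left = TRUE)
  w[beyond] <- 1 / Gt(horizon)
  if (any(!is.finite(w))) {
    stop("censoring-survivor estimate is zero at a required time; ",
         "IPCW Brier score undefined")
  }
  obs <- as.numeric(is_event)
  mean(w * (obs - risk)^2)
}

#' Royston-Sauerbrei D-statistic
#'
#' Prognostic-separation measure: the prognostic index is ranked, mapped to
#' expected standard-normal order statistics (Blom approximation
#' `qnorm((r - 3/8)/(n + 1/4))`), scaled by `kappa = sqrt(8/pi)`, and a Cox
#' model of survival on this score is fitted; D is the fitted coefficient.
#' Rank-based, hence invariant to strictly increasing transforms of the PI.
#'
#' @param pindex prognostic index (linear predictor).
#' @param time,event follow-up years and event indicator.
#' @return list `d`, `se`, `ci` (95%); a fully tied PI returns `d = 0` with a
#'   warning.
#' @export
royston_d <- function(pindex, time, event) {
  n <- length(pindex)
  if (length(unique(pindex)) < 2) {
    warning("prognostic index has no variation; D = 0 by convention")
    return(list(d = 0, se = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  r <- rank(pindex, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (n + 1 / 4)) / sqrt(8 / pi)
  fit <- survival::coxph(survival::Surv(time, event) ~ z, ties = "breslow")
  d <- unname(coef(fit))
  se <- sqrt(diag(vcov(fit)))[1]
  list(d = d, se = unname(se), ci = d + c(-1.96, 1.96) * se)
}

#' Pseudo R-squared from the D-statistic
#'
#' Closed form `R2_D = (D^2 / kappa^2) / (pi^2/6 + D^2 / kappa^2)` with
#' `kappa^2 = 8/pi`; monotone increasing in `|D|` and bounded in \[0, 1).
#'
#' @param d D-statistic value(s).
#' @return pseudo R-squared on \[0, 1).
#' @export
r2_from_d <- function(d) {
  k2 <- 8 / pi
  (d^2 / k2) / (pi^2 / 6 + d^2 / k2)
}

#' Calibration slope
#'
#' Coefficient of a Cox model with the prognostic index as its single
#' covariate; 1 indicates perfect calibration of the PI on the evaluation
#' data (guaranteed on the development data by the partial-likelihood score
#' equation).
#'
#' @param pindex prognostic index.
#' @param time,event follow-up years and event indicator.
#' @return scalar slope.
#' @export
calibration_slope <- function(pindex, time, event) {
  if (sum(event) < 1) stop("calibration slope requires at least one event")
  fit <- survival::coxph(survival::Surv(time, event) ~ pindex, ties = "breslow")
  unname(coef(fit))
}

#' Vigintile calibration table
#'
#' Patients are split into `g` equally sized groups of predicted risk
#' (vigintiles for `g = 20`); each group contributes its mean predicted risk
#' and the Kaplan-Meier observed risk `1 - KM(horizon)`, which accounts for
#' censoring before the horizon.
#'
#' @param risk predicted risks.
#' @param time,event follow-up years and event indicator.
#' @param g number of groups; requires `n >= g`.
#' @param horizon evaluation time, years.
#' @return data frame: `bin`, `n`, `events`, `mean_predicted`, `observed_km`.
#' @export
calibration_bins <- function(risk, time, event, g = 20, horizon = 2) {
  n <- length(risk)
  if (n < g) stop("need at least g = ", g, " observations for ", g, " bins")
  ord <- order(risk)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * g / n)
  out <- lapply(seq_len(g), function(b) {
    i <- grp == b
    km <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(bin = b, n = sum(i), events = sum(event[i]),
               mean_predicted = mean(risk[i]),
               observed_km = 1 - km_eval(km$time, km$surv, horizon))
  })
  do.call(rbind, out)
}

#' Full performance report
#'
#' Assembles the complete metric suite for a set of predictions on a cohort:
#' IPCW Brier score, Harrell's c with CI, Royston-Sauerbrei D with CI and its
#' pseudo R-squared, calibration slope, and the vigintile calibration table.
#'
#' @param risk predicted two-year risks.
#' @param pindex prognostic index; pass the linear predictor when available
#'   (if omitted, a monotone complementary-log-log transform of the risks is
#'   used, which leaves the rank-based metrics unchanged).
#' @param time,event follow-up years and event indicator.
#' @param g calibration groups (20).
#' @param horizon risk horizon, years (2).
#' @param label cohort/subgroup label carried in the report.
#' @param min_events below this event count the report is flagged
#'   `wide_ci = TRUE` (estimates reported but imprecise).
#' @return object of class `fbc_performance`.
#' @export
performance_report <- function(risk, pindex = NULL, time, event, g = 20,
                               horizon = 2, label = "overall",
                               min_events = 5) {
  pindex <- pindex %||% log(-log1p(-pmin(risk, 1 - 1e-12)))  # monotone surrogate
  cc <- concordance_index(risk, time, event)
  dd <- royston_d(pindex, time, event)
  structure(list(
    label = label, n = length(risk), n_events = sum(event),
    brier = brier_two_year(risk, time, event, horizon),
    c_statistic = cc,
    d_statistic = dd,
    r2_d = r2_from_d(dd$d),
    calibration_slope = calibration_slope(pindex, time, event),
    calibration_bins = if (length(risk) >= g)
      calibration_bins(risk, time, event, g, horizon) else NULL,
    wide_ci = sum(event) < min_events
  ), class = "fbc_performance")
}

#' @export
print.fbc_performance <- function(x, ...) {
  cat(sprintf("Performance [%s]: n = %d, events = %d%s\n", x$label, x$n,
              x$n_events, if (x$wide_ci) " (few events: wide CIs)" else ""))
  cat(sprintf("  Brier %.4f | c %.3f (%.3f-%.3f) | D %.2f (%.2f-%.2f) | R2_D %.2f | slope %.2f\n",
              x$brier, x$c_statistic$c, x$c_statistic$ci[1], x$c_statistic$ci[2],
              x$d_statistic$d, x$d_statistic$ci[1], x$d_statistic$ci[2],
              x$r2_d, x$calibration_slope))
  invisible(x)
}

#' Subgroup membership bands
#'
#' The reporting subgroups of the validation design: 10-year age bands from
#' 40 to 90 years (90+ collected in a final band), number of FBC panels from
#' 2 to 14 (1 and 15+ as flanking bands), and 6-month bands of the FBC time
#' span from 0 to 5 years.
#'
#' @param patients prepared patient table (needs `age_at_baseline`, `n_fbc`,
#'   `fbc_span_years`).
#' @param dimension which subgroup dimension to band on.
#' @return factor of subgroup labels aligned with `patients`.
#' @export
subgroup_bands <- function(patients, dimension = c("age_band", "n_fbc", "fbc_span")) {
  dimension <- match.arg(dimension)
  switch(dimension,
    age_band = cut(patients$age_at_baseline,
                   breaks = c(seq(40, 90, 10), Inf), right = FALSE,
                   labels = c("40-49", "50-59", "60-69", "70-79", "80-89", "90+")),
    n_fbc = factor(ifelse(patients$n_fbc < 2, "1",
                   ifelse(patients$n_fbc > 14, "15+",
                          as.character(patients$n_fbc))),
                   levels = c("1", as.character(2:14), "15+")),
    fbc_span = cut(patients$fbc_span_years, breaks = seq(0, 5, 0.5),
                   include.lowest = TRUE, right = FALSE)
  )
}

#' Performance in subgroups
#'
#' One full [performance_report()] per non-empty subgroup of the chosen
#' dimension; subgroups with fewer than `min_events` events are flagged.
#'
#' @param predictions [predict_cohort()] output for the cohort.
#' @param patients the matching prepared patient table.
#' @param dimension see [subgroup_bands()].
#' @param g calibration groups per subgroup (10 by default: subgroups are
#'   smaller than full cohorts).
#' @param min_events flag threshold.
#' @return named list of `fbc_performance` reports.
#' @export
subgroup_performance <- function(predictions, patients,
                                 dimension = c("age_band", "n_fbc", "fbc_span"),
                                 g = 10, min_events = 5) {
  dimension <- match.arg(dimension)
  band <- subgroup_bands(patients, dimension)
  out <- list()
  for (lv in levels(band)) {
    i <- which(band == lv)
    if (!length(i) || sum(patients$event[i]) < 1) next
    out[[lv]] <- performance_report(
      risk = predictions$risk_2y[i], pindex = predictions$linear_predictor[i],
      time = patients$followup_years[i], event = patients$event[i],
      g = min(g, length(i)), label = paste0(dimension, " ", lv),
      min_events = min_events)
  }
  out
}
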