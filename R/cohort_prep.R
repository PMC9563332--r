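#' Default biologically plausible ranges
#'
#' Inclusive per-analyte \[lo, hi\] bounds outside which laboratory values are
#' treated as recording errors and dropped (negative haemoglobin, platelet
#' counts in the millions, and similar).
#'
#' @return named list of `c(lo, hi)` per analyte: HB 3-25 g/dL, MCV 50-150
#'   fL, PLT 10-1500 x10^9/L.
#' @export
plausible_ranges_default <- function() {
  list(HB = c(3, 25), MCV = c(50, 150), PLT = c(10, 1500))
}

#' Drop measurements outside plausible ranges
#'
#' @param measurements data frame with `patient_id`, `analyte`, `value`,
#'   `date`.
#' @param ranges named list of `c(lo, hi)` per analyte; every analyte present
#'   in the data must have a range.
#' @return filtered measurements with attribute `"dropped"`: named per-analyte
#'   drop counts.
#' @export
apply_plausible_ranges <- function(measurements, ranges = plausible_ranges_default()) {
  an <- unique(measurements$analyte)
  missing_rng <- setdiff(an, names(ranges))
  if (length(missing_rng)) {
    stop("no plausible range configured for analyte(s): ",
         paste(missing_rng, collapse = ", "))
  }
  lo <- vapply(ranges, `[`, numeric(1), 1)[measurements$analyte]
  hi <- vapply(ranges, `[`, numeric(1), 2)[measurements$analyte]
  keep <- !is.na(measurements$value) & measurements$value >= lo & measurements$value <= hi
  dropped <- table(factor(measurements$analyte[!keep], levels = sort(an)))
  out <- measurements[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- setNames(as.integer(dropped), names(dropped))
  out
}

#' Strip measurements from the pre-outcome exclusion window
#'
#' Removes all measurements dated inside the `window_months` preceding the
#' patient's end date (diagnosis date if diagnosed, otherwise exit date), so
#' that the baseline FBC -- the most recent measurement that survives -- is
#' guaranteed to predate the outcome by at least the window length, and risk
#' is identified only from data recorded sufficiently early for intervention.
#'
#' @param measurements measurement data frame.
#' @param end_dates data frame with `patient_id` and `end_date` (Date); every
#'   patient with measurements must have a non-missing end date.
#' @param window_months exclusion window length; default 21 months
#'   (two years minus the three-month tolerance).
#' @return filtered measurements with attribute `"dropped_rows"` (count).
#' @export
apply_exclusion_window <- function(measurements, end_dates, window_months = 21) {
  ed <- end_dates$end_date[match(measurements$patient_id, end_dates$patient_id)]
  if (any(is.na(ed))) {
    stop("missing end date (diagnosis/exit) for patient(s): ",
         paste(head(unique(measurements$patient_id[is.na(ed)]), 5), collapse = ", "))
  }
  cutoff <- ed - window_months * DAYS_PER_MONTH
  keep <- as.numeric(measurements$date) <= as.numeric(cutoff)
  out <- measurements[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_rows") <- sum(!keep)
  out
}

#' Eligibility filter
#'
#' Retains patients aged at least `min_age` at baseline, with at least one
#' retained measurement of each of the three analytes, registered with their
#' practice for at least `min_registration_years` before baseline. Per-
#' criterion exclusion counts (applied sequentially) are attached for a
#' patient-flow summary.
#'
#' @param patients patient table with `patient_id`, `age_at_baseline`,
#'   `entry_date`, `baseline_date`.
#' @param measurements retained measurements (post filtering/window).
#' @param min_age minimum age at baseline, years.
#' @param min_registration_years minimum registration period before baseline.
#' @return filtered patient table with attribute `"exclusions"`.
#' @export
filter_eligible <- function(patients, measurements, min_age = 40,
                            min_registration_years = 1) {
  excl <- c(age_under_min = 0L, missing_analyte = 0L, short_registration = 0L)

  ok_age <- patients$age_at_baseline >= min_age
  excl["age_under_min"] <- sum(!ok_age)
  patients <- patients[ok_age, , drop = FALSE]

  have <- table(factor(measurements$patient_id, levels = patients$patient_id),
                factor(measurements$analyte, levels = names(FBC_ANALYTES)))
  ok_an <- rowSums(have > 0) == length(FBC_ANALYTES)
  excl["missing_analyte"] <- sum(!ok_an)
  patients <- patients[ok_an, , drop = FALSE]

  reg_years <- as.numeric(patients$baseline_date - patients$entry_date) / DAYS_PER_YEAR
  ok_reg <- reg_years >= min_registration_years
  excl["short_registration"] <- sum(!ok_reg)
  patients <- patients[ok_reg, , drop = FALSE]

  rownames(patients) <- NULL
  attr(patients, "exclusions") <- excl
  patients
}

#' Outcome and censoring definition
#'
#' A patient is a case (`event = 1`) if a colorectal cancer diagnosis falls
#' within `outcome_window_months` (default 27: two years plus the three-month
#' tolerance) after baseline. Otherwise follow-up is censored at the earliest
#' of the exit date (leaving the practice, death, other-cancer diagnosis or
#' the data-cut, whichever the record carries) and `horizon_years` after
#' baseline; diagnoses beyond the outcome window are likewise censored at the
#' horizon.
#'
#' @param baseline_date,diagnosis_date,exit_date Date vectors (diagnosis NA
#'   when never diagnosed).
#' @param outcome_window_months width of the case window after baseline.
#' @param horizon_years administrative follow-up cap, years.
#' @return data frame with `event` (0/1) and `followup_years`.
#' @export
define_outcome <- function(baseline_date, diagnosis_date, exit_date,
                           outcome_window_months = 27, horizon_years = 2) {
  if (any(is.na(baseline_date))) stop("baseline_date must be set for all patients")
  if (any(!is.na(diagnosis_date) & diagnosis_date < baseline_date)) {
    stop("diagnosis before baseline: exclusion-window contract violated")
  }
  win_days <- outcome_window_months * DAYS_PER_MONTH
  is_case <- !is.na(diagnosis_date) &
    as.numeric(diagnosis_date - baseline_date) <= win_days
  censor_date <- pmin(exit_date, baseline_date + horizon_years * DAYS_PER_YEAR)
  end <- as.Date(ifelse(is_case, diagnosis_date, censor_date), origin = "1970-01-01")
  data.frame(event = as.integer(is_case),
             followup_years = as.numeric(end - baseline_date) / DAYS_PER_YEAR)
}

#' Prepare a raw cohort for joint-model fitting
#'
#' Applies the full study-design mechanics to raw patient and measurement
#' tables: plausible-range filtering; the pre-outcome exclusion window;
#' baseline anchoring (most recent surviving FBC, time 5 on the longitudinal
#' clock) with the five-year window mapped as
#' `time = 5 - (baseline_date - date)/365.25` and measurements older than the
#' window dropped; same-day duplicate values of one analyte averaged;
#' eligibility filtering; and the outcome/censoring definition. Ages are
#' recomputed at the derived baseline from `birth_year`.
#'
#' @param patients raw patient table (`patient_id`, `sex`, `birth_year`,
#'   `entry_date`, `exit_date`, `exit_reason`, `diagnosis_date`).
#' @param measurements raw measurement table (`patient_id`, `analyte`,
#'   `value`, `date`).
#' @param ranges plausible ranges, see [apply_plausible_ranges()].
#' @param exclusion_window_months see [apply_exclusion_window()].
#' @param outcome_window_months,horizon_years see [define_outcome()].
#' @param window_years length of the longitudinal window (5).
#' @param min_age,min_registration_years see [filter_eligible()].
#' @return object of class `fbc_prepared`: list with `patients` (one row per
#'   retained patient, with `baseline_date`, `age_at_baseline`, `event`,
#'   `followup_years`, `n_fbc`, `fbc_span_years`), `measurements` (with
#'   `window_time`), and `flow` (named exclusion counts).
#' @export
prepare_cohort <- function(patients, measurements,
                           ranges = plausible_ranges_default(),
                           exclusion_window_months = 21,
                           outcome_window_months = 27,
                           horizon_years = 2,
                           window_years = 5,
                           min_age = 40,
                           min_registration_years = 1) {
  flow <- list(n_patients_in = nrow(patients), n_measurements_in = nrow(measurements))

  measurements <- apply_plausible_ranges(measurements, ranges)
  flow$implausible_dropped <- attr(measurements, "dropped")

  end_dates <- data.frame(
    patient_id = patients$patient_id,
    end_date = as.Date(ifelse(is.na(patients$diagnosis_date),
                              patients$exit_date, patients$diagnosis_date),
                       origin = "1970-01-01")
  )
  measurements <- apply_exclusion_window(measurements, end_dates,
                                         exclusion_window_months)
  flow$exclusion_window_dropped <- attr(measurements, "dropped_rows")

  has_meas <- patients$patient_id %in% measurements$patient_id
  flow$no_remaining_fbc <- sum(!has_meas)
  patients <- patients[has_meas, , drop = FALSE]

  # baseline = most recent surviving measurement; five-year clock
  bl <- aggregate(as.numeric(measurements$date),
                  by = list(patient_id = measurements$patient_id), FUN = max)
  patients$baseline_date <- as.Date(bl$x[match(patients$patient_id, bl$patient_id)],
                                    origin = "1970-01-01")
  patients$age_at_baseline <-
    as.integer(format(patients$baseline_date, "%Y")) - patients$birth_year

  mb <- patients$baseline_date[match(measurements$patient_id, patients$patient_id)]
  measurements$window_time <- window_years -
    as.numeric(mb - measurements$date) / DAYS_PER_YEAR
  in_window <- measurements$window_time >= 0
  flow$outside_window_dropped <- sum(!in_window)
  measurements <- measurements[in_window, , drop = FALSE]

  # same-day duplicates of one analyte: average (deterministic tie-break)
  key <- paste(measurements$patient_id, measurements$analyte, measurements$date)
  if (anyDuplicated(key)) {
    measurements <- aggregate(value ~ patient_id + analyte + date + window_time,
                              data = measurements, FUN = mean)
  }

  patients <- filter_eligible(patients, measurements, min_age,
                              min_registration_years)
  flow$eligibility <- attr(patients, "exclusions")
  measurements <- measurements[measurements$patient_id %in% patients$patient_id, ,
                               drop = FALSE]

  oc <- define_outcome(patients$baseline_date, patients$diagnosis_date,
                       patients$exit_date, outcome_window_months, horizon_years)
  patients$event <- oc$event
  patients$followup_years <- oc$followup_years

  # per-patient FBC panel count and time span (for subgroup reporting)
  dts <- unique(measurements[, c("patient_id", "date", "window_time")])
  cnt <- table(factor(dts$patient_id, levels = patients$patient_id))
  patients$n_fbc <- as.integer(cnt)
  tmin <- aggregate(window_time ~ patient_id, data = dts, FUN = min)
  patients$fbc_span_years <- window_years -
    tmin$window_time[match(patients$patient_id, tmin$patient_id)]

  flow$n_patients_out <- nrow(patients)
  flow$n_measurements_out <- nrow(measurements)
  flow$n_events <- sum(patients$event)

  measurements <- measurements[order(measurements$patient_id, measurements$date,
                                     measurements$analyte), ]
  rownames(measurements) <- NULL
  rownames(patients) <- NULL
  attr(patients, "exclusions") <- NULL

  structure(list(patients = patients, measurements = measurements, flow = flow),
            class = "fbc_prepared")
}

#' @export
print.fbc_prepared <- function(x, ...) {
  cat(sprintf("Prepared cohort: %d patients, %d measurements, %d events (%.2f%%)\n",
              nrow(x$patients), nrow(x$measurements), x$flow$n_events,
              100 * x$flow$n_events / max(nrow(x$patients), 1)))
  invisible(x)
}
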