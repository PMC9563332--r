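mk_patient <- function(id = "P1", birth_year = 1950,
                       entry = as.Date("2000-01-01"),
                       exit = as.Date("2012-01-01"),
                       diagnosis = as.Date(NA)) {
  data.frame(patient_id = id, sex = "male", birth_year = birth_year,
             entry_date = entry, exit_date = exit, diagnosis_date = diagnosis,
             stringsAsFactors = FALSE)
}

mk_meas <- function(id, analyte, value, date) {
  data.frame(patient_id = id, analyte = analyte, value = value,
             date = as.Date(date), stringsAsFactors = FALSE)
}

test_that("plausible-range filtering drops impossible values and logs counts", {
  m <- rbind(mk_meas("P1", "HB", -1, "2010-01-01"),      # negative: dropped
             mk_meas("P1", "HB", 30, "2010-02-01"),      # above default hi 25
             mk_meas("P1", "HB", 14.2, "2010-03-01"),
             mk_meas("P1", "PLT", 250, "2010-03-01"))
  out <- apply_plausible_ranges(m)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "dropped"), c(HB = 2L, PLT = 0L))

  ok <- apply_plausible_ranges(mk_meas("P1", "MCV", 92, "2010-01-01"))
  expect_equal(ok$value, 92)

  expect_error(apply_plausible_ranges(mk_meas("P1", "WBC", 7, "2010-01-01")),
               "WBC")
})

test_that("exclusion window strips recent FBCs and re-anchors baseline", {
  # diagnosis at month 0; FBCs at months -6, -12, -30 before it; window 21
  diag <- as.Date("2012-01-01")
  m <- mk_meas("P1", "HB", c(14, 14.5, 15),
               diag - round(c(6, 12, 30) * 365.25 / 12))
  out <- apply_exclusion_window(m, data.frame(patient_id = "P1", end_date = diag),
                                window_months = 21)
  expect_equal(nrow(out), 1)
  expect_equal(out$date, diag - round(30 * 365.25 / 12))
  expect_equal(attr(out, "dropped_rows"), 2L)

  # all FBCs older than the window: identity
  old <- mk_meas("P1", "HB", c(13, 14), diag - c(800, 900))
  expect_equal(nrow(apply_exclusion_window(
    old, data.frame(patient_id = "P1", end_date = diag), 21)), 2)

  # a patient whose single FBC is 10 months before the end date is left
  # with nothing and is then dropped by prepare_cohort
  single <- mk_meas("P2", "HB", 13, diag - round(10 * 365.25 / 12))
  out2 <- apply_exclusion_window(single,
                                 data.frame(patient_id = "P2", end_date = diag), 21)
  expect_equal(nrow(out2), 0)

  expect_error(apply_exclusion_window(
    m, data.frame(patient_id = "P9", end_date = diag)), "missing end date")
})

test_that("eligibility retains 40+, all-three-analyte, 1y-registered patients", {
  pats <- rbind(mk_patient("P1", birth_year = 1973),  # 39 at 2012 baseline
                mk_patient("P2", birth_year = 1950),
                mk_patient("P3", birth_year = 1940),
                mk_patient("P4", birth_year = 1945,
                           entry = as.Date("2011-10-01")))  # < 1y registered
  pats$baseline_date <- as.Date("2012-06-01")
  pats$age_at_baseline <- 2012 - pats$birth_year
  m <- rbind(mk_meas("P1", "HB", 14, "2011-01-01"),
             mk_meas("P1", "MCV", 90, "2011-01-01"),
             mk_meas("P1", "PLT", 250, "2011-01-01"),
             mk_meas("P2", "HB", 14, "2011-01-01"),
             mk_meas("P2", "MCV", 90, "2011-01-01"),
             mk_meas("P2", "PLT", 250, "2011-01-01"),
             mk_meas("P3", "HB", 14, "2011-01-01"),   # no PLT: excluded
             mk_meas("P3", "MCV", 90, "2011-01-01"),
             mk_meas("P4", "HB", 14, "2012-01-01"),
             mk_meas("P4", "MCV", 90, "2012-01-01"),
             mk_meas("P4", "PLT", 250, "2012-01-01"))
  out <- filter_eligible(pats, m)
  expect_equal(out$patient_id, "P2")
  expect_equal(attr(out, "exclusions"),
               c(age_under_min = 1L, missing_analyte = 1L, short_registration = 1L))

  # idempotence / identity when everyone qualifies
  again <- filter_eligible(out, m)
  expect_equal(again$patient_id, out$patient_id)
  expect_equal(attr(again, "exclusions"),
               c(age_under_min = 0L, missing_analyte = 0L, short_registration = 0L))
})

test_that("outcome definition applies the 27-month case window and 2-year cap", {
  bl <- as.Date("2010-01-01")
  mo <- function(k) bl + round(k * 365.25 / 12)

  # diagnosis 23 months after baseline: a case
  oc <- define_outcome(bl, mo(23), mo(23))
  expect_equal(oc$event, 1L)
  expect_equal(oc$followup_years, 23 / 12, tolerance = 0.01)

  # no diagnosis, leaves practice at 30 months: censored at 24 months
  oc2 <- define_outcome(bl, as.Date(NA), mo(30))
  expect_equal(oc2$event, 0L)
  expect_equal(oc2$followup_years, 2, tolerance = 1e-9)

  # death at 25 months without diagnosis: censored at 24 months
  oc3 <- define_outcome(bl, as.Date(NA), mo(25))
  expect_equal(oc3$followup_years, 2)

  # diagnosis beyond the 27-month window: treated as a censored non-case
  oc4 <- define_outcome(bl, mo(30), mo(30))
  expect_equal(oc4$event, 0L)
  expect_equal(oc4$followup_years, 2)

  expect_error(define_outcome(bl, bl - 10, bl - 10), "before baseline")
})

test_that("window-time mapping is affine with baseline at 5", {
  # a patient whose earliest FBC falls three months after the window start
  bl <- as.Date("2022-06-15")
  pats <- mk_patient("P1", birth_year = 1950, exit = bl + 900)
  m <- rbind(mk_meas("P1", "HB", 14, "2017-09-15"),
             mk_meas("P1", "MCV", 90, "2017-09-15"),
             mk_meas("P1", "PLT", 250, "2017-09-15"),
             mk_meas("P1", "HB", 13.5, bl),
             mk_meas("P1", "MCV", 91, bl),
             mk_meas("P1", "PLT", 240, bl))
  prep <- prepare_cohort(pats, m)
  expect_equal(sort(unique(prep$measurements$window_time)),
               c(0.25, 5), tolerance = 0.02)
  expect_equal(prep$patients$baseline_date, bl)
  expect_equal(prep$patients$age_at_baseline, 72)
})

test_that("same-day duplicate values of one analyte are averaged", {
  bl <- as.Date("2012-01-01")
  pats <- mk_patient("P1", exit = bl + 900)
  m <- rbind(mk_meas("P1", "HB", c(14, 15), c(bl, bl)),
             mk_meas("P1", "MCV", 90, bl),
             mk_meas("P1", "PLT", 250, bl),
             mk_meas("P1", "HB", 13, bl - 400))
  prep <- prepare_cohort(pats, m)
  hb5 <- prep$measurements[prep$measurements$analyte == "HB" &
                             prep$measurements$window_time == 5, ]
  expect_equal(nrow(hb5), 1)
  expect_equal(hb5$value, 14.5)
})

test_that("preparation is idempotent on an already-clean cohort", {
  sp <- sim_prep(400, "male", seed = 77)
  prep <- sp$prep
  # feed the prepared tables back through: nothing more should change
  pats2 <- prep$patients
  pats2$entry_date <- sp$cohort$patients$entry_date[
    match(pats2$patient_id, sp$cohort$patients$patient_id)]
  pats2$exit_date <- sp$cohort$patients$exit_date[
    match(pats2$patient_id, sp$cohort$patients$patient_id)]
  pats2$diagnosis_date <- sp$cohort$patients$diagnosis_date[
    match(pats2$patient_id, sp$cohort$patients$patient_id)]
  prep2 <- prepare_cohort(pats2, prep$measurements[, c("patient_id", "analyte",
                                                       "value", "date")])
  expect_equal(nrow(prep2$patients), nrow(prep$patients))
  expect_equal(prep2$measurements$value, prep$measurements$value)
  expect_equal(prep2$patients$event, prep$patients$event)
})
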