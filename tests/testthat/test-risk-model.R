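test_that("Cox fit matches brute-force partial-likelihood maximisation on a toy", {
  # 10 patients, two informative covariates; age and platelet deviation held
  # constant so their coefficients are pinned at zero
  time <- c(0.5, 0.9, 1.3, 1.7, 2.0, 1.1, 1.5, 1.9, 0.7, 2.0)
  event <- c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0)
  dev <- data.frame(d_hb = c(-1.2, -0.5, 0.3, -0.8, 0.9, -0.2, 0.5, -1.5, 0.1, 0.7),
                    d_mcv = c(-3, 1, 2, -2, 4, 0, -1, -4, 2, 3),
                    d_plt = 0)
  suppressWarnings(fit <- fit_cox(time, event, age = rep(60, 10), dev))
  expect_equal(unname(fit$coef[c("age2", "age2log", "d_plt")]), c(0, 0, 0))

  X <- as.matrix(dev[, c("d_hb", "d_mcv")])
  orc <- oracle_cox_fit(X, time, event)
  expect_equal(unname(fit$coef[c("d_hb", "d_mcv")]), orc$par, tolerance = 1e-4)
  # partial likelihood at the package optimum equals the oracle optimum
  expect_equal(oracle_cox_loglik(fit$coef[c("d_hb", "d_mcv")], X, time, event),
               -orc$value, tolerance = 1e-6)
})

test_that("all-constant covariates yield all-zero coefficients", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 0, 1)
  dev <- data.frame(d_hb = 1, d_mcv = 2, d_plt = 3)
  expect_warning(fit <- fit_cox(time, event, age = rep(50, 4), dev), "constant")
  expect_equal(unname(fit$coef), rep(0, 5))
  expect_error(fit_cox(c(1, 2), c(0, 0), age = c(50, 60),
                       data.frame(d_hb = 1:2, d_mcv = 0, d_plt = 0)),
               "at least 2 events")
})

test_that("Breslow baseline with null covariates is exp(-Nelson-Aalen)", {
  time <- c(1, 2, 3, 4, 5); event <- c(1, 1, 0, 1, 0)
  # Nelson-Aalen at t=2: 1/5 + 1/4
  expect_equal(breslow_baseline_survival(time, event, rep(0, 5), horizon = 2),
               exp(-(1 / 5 + 1 / 4)))
  # no events before the horizon
  expect_equal(breslow_baseline_survival(time, event, rep(0, 5), horizon = 0.5), 1.0)
  expect_warning(s <- breslow_baseline_survival(time, event, rep(0, 5), horizon = 9),
                 "beyond last follow-up")
  expect_equal(s, exp(-(1 / 5 + 1 / 4 + 1 / 2)))
})

test_that("Breslow baseline agrees with survival::basehaz on a covariate fit", {
  set.seed(21)
  n <- 80
  x <- rnorm(n)
  time <- rexp(n, exp(0.7 * x)); event <- rbinom(n, 1, 0.7)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  lp_c <- unname(predict(fit, type = "lp"))  # mean-centred by construction
  bh <- survival::basehaz(fit, centered = TRUE)
  tau <- stats::median(time)
  H_ref <- max(bh$hazard[bh$time <= tau])
  expect_equal(breslow_baseline_survival(time, event, lp_c, horizon = tau),
               exp(-H_ref), tolerance = 1e-10)
})

test_that("absolute risk follows the Breslow survival complement", {
  params <- list(coef = c(age2 = 0, age2log = 0, d_hb = log(0.868),
                          d_mcv = 0, d_plt = 0),
                 covariate_means = c(age2 = 3600, age2log = 3600 * log(60),
                                     d_hb = 0, d_mcv = 0, d_plt = 0),
                 s0_2y = 0.999941, age_scale = 1)
  # covariates at their means: risk = 1 - s0
  at_mean <- two_year_risk(params, age = 60,
                           data.frame(d_hb = 0, d_mcv = 0, d_plt = 0))
  expect_equal(at_mean$linear_predictor, 0)
  expect_equal(at_mean$risk_2y, 5.9e-5, tolerance = 1e-9)

  # a 1 g/dL haemoglobin decline multiplies the hazard by 1/0.868
  low_hb <- two_year_risk(params, age = 60,
                          data.frame(d_hb = -1, d_mcv = 0, d_plt = 0))
  expect_equal(low_hb$risk_2y, 1 - 0.999941^(1 / 0.868), tolerance = 1e-12)
  expect_equal(low_hb$risk_2y, 6.8e-5, tolerance = 1e-2)

  # risk is strictly increasing in the linear predictor and bounded in (0,1)
  lps <- seq(-3, 8, 0.5)
  risks <- 1 - params$s0_2y^exp(lps)
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks > 0 & risks < 1))
})

test_that("hazard ratios are invariant to rescaling the follow-up clock", {
  sp <- sim_prep(1500, "male", seed = 8, multiplier = 30)
  p <- sp$prep$patients
  tr <- sp$cohort$truth[match(p$patient_id, sp$cohort$truth$patient_id), ]
  dev <- data.frame(d_hb = tr$d_hb, d_mcv = tr$d_mcv, d_plt = tr$d_plt)
  f1 <- fit_cox(p$followup_years, p$event, p$age_at_baseline, dev)
  f2 <- fit_cox(p$followup_years * 3.7, p$event, p$age_at_baseline, dev)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

# a small fitted bundle shared by the prediction tests
sp_bundle <- sim_prep(2000, "male", seed = 15, multiplier = 10)
bundle <- suppressWarnings(fit_joint_pipeline(sp_bundle$prep))

test_that("the two-stage pipeline returns a complete, coherent bundle", {
  expect_s3_class(bundle, "fbc_joint_model")
  expect_named(bundle$longitudinal, c("HB", "MCV", "PLT"))
  expect_true(bundle$cox$s0_2y > 0 && bundle$cox$s0_2y < 1)
  expect_equal(bundle$meta$n, nrow(sp_bundle$prep$patients))
  expect_equal(nrow(bundle$development), bundle$meta$n)
  # development risks reproduce through predict_cohort on the same data
  pred <- predict_cohort(bundle, sp_bundle$prep)
  expect_equal(pred$risk_2y, bundle$development$risk_2y, tolerance = 1e-12)
})

test_that("a history on the population curves gives the age-only risk", {
  hb <- bundle$longitudinal$HB
  dates <- as.Date("2012-06-01") - round(c(0, 1, 2.5, 4.8) * 365.25)
  age <- 70
  hist <- do.call(rbind, lapply(c("HB", "MCV", "PLT"), function(a) {
    par <- bundle$longitudinal[[a]]
    tt <- 5 - as.numeric(max(dates) - dates) / 365.25
    data.frame(analyte = a, value = population_trajectory(par, age, tt),
               date = dates, stringsAsFactors = FALSE)
  }))
  out <- predict_patient(bundle, hist, age = age)
  expect_equal(unname(unlist(out[c("d_hb", "d_mcv", "d_plt")])), c(0, 0, 0),
               tolerance = 1e-9)
  base <- two_year_risk(bundle$cox, age, data.frame(d_hb = 0, d_mcv = 0, d_plt = 0))
  expect_equal(out$risk_2y, base$risk_2y, tolerance = 1e-12)
})

test_that("a newly observed low haemoglobin raises the predicted risk", {
  # pin the haemoglobin log-HR at its published negative value so the sign
  # argument is deterministic
  b2 <- bundle
  b2$cox$coef["d_hb"] <- log(0.868)
  age <- 70
  dates <- as.Date("2012-06-01") - round(c(0.5, 2, 4) * 365.25)
  hist <- do.call(rbind, lapply(c("HB", "MCV", "PLT"), function(a) {
    par <- b2$longitudinal[[a]]
    tt <- 5 - as.numeric(max(dates) - dates) / 365.25
    data.frame(analyte = a, value = population_trajectory(par, age, tt),
               date = dates, stringsAsFactors = FALSE)
  }))
  r0 <- predict_patient(b2, hist, age = age)
  # dynamic update: a new, clearly low HB measurement arrives
  new_date <- as.Date("2012-09-01")
  mu_new <- population_trajectory(b2$longitudinal$HB, age, 5)
  hist2 <- rbind(hist, data.frame(analyte = "HB", value = mu_new - 2,
                                  date = new_date, stringsAsFactors = FALSE))
  r1 <- predict_patient(b2, hist2, age = age)
  expect_lt(r1$d_hb, 0)
  expect_gt(r1$risk_2y, r0$risk_2y)

  expect_error(predict_patient(b2, hist[0, ], age = 60), "empty")
})
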