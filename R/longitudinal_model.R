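#' Longitudinal sub-model parameters
#'
#' Container for one analyte's linear mixed model: fixed effects on the
#' linear-spline design (see [analyte_spline_spec()]), a 2x2 unstructured
#' covariance of the patient-level random intercept and random time slope,
#' and the residual variance.
#'
#' @param analyte `"HB"`, `"MCV"` or `"PLT"`.
#' @param beta named numeric vector of fixed effects; names must match the
#'   design columns produced by `longitudinal_design()` for the spec.
#' @param G 2x2 symmetric positive semi-definite random-effects covariance,
#'   order (intercept, slope).
#' @param sigma2 residual variance (>= 0; must be > 0 for fitting).
#' @param spec spline specification; defaults to [analyte_spline_spec()] for
#'   the analyte.
#' @param n_obs,n_patients,logLik,converged fit metadata (optional).
#' @return object of class `fbc_longit_params`.
#' @export
longit_params <- function(analyte, beta, G, sigma2,
                          spec = analyte_spline_spec(analyte),
                          n_obs = NA_integer_, n_patients = NA_integer_,
                          logLik = NA_real_, converged = NA) {
  G <- as.matrix(G)
  stopifnot(all(dim(G) == c(2, 2)), isTRUE(all.equal(G, t(G), tolerance = 1e-8)))
  if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values <
          -1e-8 * max(abs(G), 1))) {
    stop(sprintf("random-effects covariance for analyte %s is not positive semi-definite",
                 analyte))
  }
  if (sigma2 < 0) stop("residual variance must be non-negative")
  dimnames(G) <- list(c("intercept", "slope"), c("intercept", "slope"))
  structure(list(analyte = analyte, beta = beta, G = G, sigma2 = sigma2,
                 spec = spec, n_obs = n_obs, n_patients = n_patients,
                 logLik = logLik, converged = converged),
            class = "fbc_longit_params")
}

#' Random-effects covariance from standard deviations and correlation
#'
#' @param sd_intercept,sd_slope non-negative standard deviations of the
#'   random intercept (analyte units) and random time slope (units/year).
#' @param corr correlation in \[-1, 1\].
#' @return 2x2 covariance matrix.
#' @export
re_cov <- function(sd_intercept, sd_slope, corr = 0) {
  stopifnot(sd_intercept >= 0, sd_slope >= 0, abs(corr) <= 1)
  cv <- corr * sd_intercept * sd_slope
  matrix(c(sd_intercept^2, cv, cv, sd_slope^2), 2, 2)
}

#' Population mean trajectory
#'
#' Fixed-effects prediction of the analyte value at given baseline age and
#' time on the five-year longitudinal clock (0 = window start, 5 = baseline).
#'
#' @param params [longit_params()] object.
#' @param age age at baseline, years (recycled against `time`).
#' @param time time in years on \[0, 5\] (values outside are extrapolated
#'   linearly, as used when generating decoy measurements).
#' @return numeric vector of population mean values.
#' @export
population_trajectory <- function(params, age, time) {
  k <- max(length(age), length(time))
  X <- longitudinal_design(rep_len(age, k), rep_len(time, k), params$spec)
  miss <- setdiff(colnames(X), names(params$beta))
  if (length(miss)) stop("fixed-effect names missing from params: ",
                         paste(miss, collapse = ", "))
  drop(X %*% params$beta[colnames(X)])
}

#' Fit one analyte's mixed-effects sub-model
#'
#' REML fit of `value ~ age splines + time splines (+ age x time for HB) +
#' (1 + time | patient)` on a prepared cohort, via [lme4::lmer()]. Age is age
#' at baseline (constant within patient), time is the position of each
#' measurement on the five-year window with baseline at 5.
#'
#' If the data are exactly interpolated by the fixed effects (residual
#' variance numerically zero, as in noise-free simulations) the variance
#' components are not estimable; the fit then falls back to ordinary least
#' squares with zero random-effects covariance, which returns the exact
#' fixed effects.
#'
#' @param prepared a prepared cohort (see [prepare_cohort()]), or any list
#'   with `measurements` (patient_id, analyte, value, window_time) and
#'   `patients` (patient_id, age_at_baseline).
#' @param analyte which analyte to fit.
#' @param spec spline specification; default [analyte_spline_spec()].
#' @return [longit_params()] with fit metadata.
#' @export
fit_mixed_model <- function(prepared, analyte = names(FBC_ANALYTES),
                            spec = NULL) {
  analyte <- match.arg(analyte)
  spec <- spec %||% analyte_spline_spec(analyte)
  m <- prepared$measurements[prepared$measurements$analyte == analyte, ]
  if (!nrow(m)) stop("no measurements for analyte ", analyte)
  age <- prepared$patients$age_at_baseline[
    match(m$patient_id, prepared$patients$patient_id)]
  X <- longitudinal_design(age, m$window_time, spec)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  dat <- data.frame(value = m$value, patient_id = m$patient_id,
                    time = m$window_time, check.names = FALSE)
  dat <- cbind(dat, as.data.frame(X[, -1, drop = FALSE]))
  fixed_terms <- paste(sprintf("`%s`", colnames(X)[-1]), collapse = " + ")

  # Degenerate noise-free data: variance components vanish; exact OLS fit.
  ols <- lm.fit(X, dat$value)
  if (mean(ols$residuals^2) < 1e-10 * max(var(dat$value), 1e-12)) {
    beta <- setNames(ols$coefficients, colnames(X))
    return(longit_params(analyte, beta, G = matrix(0, 2, 2), sigma2 = 0,
                         spec = spec, n_obs = nrow(dat),
                         n_patients = length(unique(dat$patient_id)),
                         logLik = NA_real_, converged = TRUE))
  }

  fml <- stats::as.formula(paste("value ~", fixed_terms, "+ (1 + time | patient_id)"))
  fit <- lme4::lmer(fml, data = dat, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- lme4::VarCorr(fit)$patient_id
  G <- matrix(as.numeric(vc[1:2, 1:2]), 2, 2)
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  conv <- length(fit@optinfo$conv$lme4) == 0
  if (!conv) warning("mixed-model fit for ", analyte,
                     " raised convergence diagnostics: ",
                     paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  longit_params(analyte, beta, G = G, sigma2 = stats::sigma(fit)^2, spec = spec,
                n_obs = nrow(dat), n_patients = length(unique(dat$patient_id)),
                logLik = as.numeric(logLik(fit)), converged = conv)
}

#' Best linear unbiased prediction of a patient's random effects
#'
#' Conditional mean of the random intercept and slope given the patient's
#' residuals from the population trajectory:
#' `b = G Z' (Z G Z' + sigma2 I)^-1 r`, computed through the equivalent 2x2
#' system `b = G (sigma2 I + Z'Z G)^-1 Z'r`, which remains valid when `G` is
#' singular (full shrinkage: `G -> 0` gives `b -> 0`).
#'
#' @param params fitted [longit_params()].
#' @param time measurement times on the five-year window.
#' @param value measured analyte values at those times.
#' @param age patient's age at baseline (scalar).
#' @return named numeric vector `c(b0, b1)`: intercept and slope deviations.
#' @export
estimate_random_effects <- function(params, time, value, age) {
  if (!length(time)) {
    warning("no measurements for analyte ", params$analyte,
            "; falling back to the population mean (zero random effects)")
    return(c(b0 = 0, b1 = 0))
  }
  if (all(params$G == 0)) return(c(b0 = 0, b1 = 0))  # full shrinkage
  r <- value - population_trajectory(params, age, time)
  A <- matrix(c(length(time), sum(time), sum(time), sum(time^2)), 2, 2)
  cc <- c(sum(r), sum(r * time))
  M <- params$sigma2 * diag(2) + A %*% params$G
  b <- unname(drop(params$G %*% solve(M, cc)))
  c(b0 = b[1], b1 = b[2])
}

# Vectorised BLUPs for a whole cohort: per-patient 2x2 solves written in
# closed form over rowsum-aggregated sufficient statistics.
estimate_random_effects_all <- function(params, prepared) {
  pid <- prepared$patients$patient_id
  if (all(params$G == 0)) {
    return(data.frame(patient_id = pid, b0 = 0, b1 = 0, stringsAsFactors = FALSE))
  }
  m <- prepared$measurements[prepared$measurements$analyte == params$analyte, ]
  age <- prepared$patients$age_at_baseline[match(m$patient_id, pid)]
  r <- m$value - population_trajectory(params, age, m$window_time)
  g <- factor(m$patient_id, levels = pid)
  S <- rowsum(cbind(n = 1, St = m$window_time, Stt = m$window_time^2,
                    Sr = r, Str = r * m$window_time), g)
  S[is.na(S)] <- 0
  G <- params$G; s2 <- params$sigma2
  # M = s2 I + A G with A = [n St; St Stt]
  m11 <- s2 + S[, "n"] * G[1, 1] + S[, "St"] * G[2, 1]
  m12 <- S[, "n"] * G[1, 2] + S[, "St"] * G[2, 2]
  m21 <- S[, "St"] * G[1, 1] + S[, "Stt"] * G[2, 1]
  m22 <- s2 + S[, "St"] * G[1, 2] + S[, "Stt"] * G[2, 2]
  det <- m11 * m22 - m12 * m21
  if (any(abs(det) < 1e-300)) stop("degenerate BLUP system (zero variances?)")
  # x = M^-1 c
  x1 <- (m22 * S[, "Sr"] - m12 * S[, "Str"]) / det
  x2 <- (-m21 * S[, "Sr"] + m11 * S[, "Str"]) / det
  b0 <- G[1, 1] * x1 + G[1, 2] * x2
  b1 <- G[2, 1] * x1 + G[2, 2] * x2
  none <- S[, "n"] == 0
  if (any(none)) {
    warning(sum(none), " patient(s) without ", params$analyte,
            " measurements; using population-mean fallback (zero random effects)")
    b0[none] <- 0; b1[none] <- 0
  }
  data.frame(patient_id = pid, b0 = b0, b1 = b1, stringsAsFactors = FALSE)
}

#' Trend deviation at the baseline time
#'
#' A patient's model-implied departure from the average population
#' trajectory at the baseline time: `b0 + b1 * t_baseline` in analyte units.
#' This is the covariate the survival sub-model acts on.
#'
#' @param re random effects as returned by [estimate_random_effects()]
#'   (vector `c(b0, b1)`) or a data frame with `b0`, `b1` columns.
#' @param t_baseline baseline position on the longitudinal clock (5 in the
#'   standard five-year design).
#' @return numeric deviation(s), analyte units.
#' @export
trend_deviation <- function(re, t_baseline = 5) {
  if (is.data.frame(re)) re$b0 + re$b1 * t_baseline
  else unname(re["b0"] + re["b1"] * t_baseline)
}

#' @export
print.fbc_longit_params <- function(x, ...) {
  cat(sprintf("Longitudinal sub-model [%s]: %d fixed effects, n = %s obs / %s patients\n",
              x$analyte, length(x$beta),
              format(x$n_obs), format(x$n_patients)))
  cat("  sd(intercept) =", format(sqrt(x$G[1, 1]), digits = 4),
      " sd(slope) =", format(sqrt(x$G[2, 2]), digits = 4),
      " resid sd =", format(sqrt(x$sigma2), digits = 4), "\n")
  invisible(x)
}
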