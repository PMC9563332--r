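#' Linear spline basis
#'
#' Piecewise-linear basis used for the fixed effects of the longitudinal
#' sub-models: the identity term plus one hinge term `pmax(x - k, 0)` per
#' knot, so the fitted curve is continuous with a slope change at each knot.
#'
#' @param x numeric vector of predictor values (age in years, or time in
#'   years on the five-year longitudinal clock).
#' @param knots strictly increasing numeric vector of knot locations, in the
#'   units of `x`. May be empty, in which case the basis is just `x`.
#' @return numeric matrix with `length(knots) + 1` columns named
#'   `x, x_k<knot1>, ...`.
#' @examples
#' linear_spline_basis(75, c(60, 70, 80))  # 75, 15, 5, 0
#' @export
linear_spline_basis <- function(x, knots = numeric(0)) {
  if (length(knots) && any(diff(knots) <= 0)) {
    stop("spline knots must be strictly increasing")
  }
  out <- matrix(as.numeric(x), ncol = 1)
  for (k in knots) out <- cbind(out, pmax(x - k, 0))
  colnames(out) <- c("x", if (length(knots)) paste0("x_k", knots))
  out
}

#' Fractional-polynomial age terms for the survival sub-model
#'
#' Age enters the Cox sub-model through the repeated-power-2 fractional
#' polynomial pair `(a^2, a^2 log a)` with `a = age / age_scale`. With the
#' default `age_scale = 1` the coefficients are per squared year of age.
#'
#' @param age age in years at baseline; must be positive.
#' @param age_scale positive divisor applied to age before the transform.
#' @return two-column matrix with columns `age2` and `age2log`.
#' @export
fp_age_terms <- function(age, age_scale = 1) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0)) {
    stop("age must be positive and finite for the fractional-polynomial transform")
  }
  if (age_scale <= 0) stop("age_scale must be positive")
  a <- age / age_scale
  cbind(age2 = a^2, age2log = a^2 * log(a))
}

#' Spline specifications for the three FBC analytes
#'
#' Default fixed-effect structure of the longitudinal sub-models: linear
#' splines in age at baseline with knots at 60, 70 and 80 years for
#' haemoglobin, 55 for MCV and 60 for platelets; a linear spline in time on
#' the five-year clock with a knot at year 3 for every analyte; and an
#' age-by-time interaction for haemoglobin only.
#'
#' @param analyte one of `"HB"`, `"MCV"`, `"PLT"`.
#' @return list with elements `analyte`, `age_knots`, `time_knots`,
#'   `age_time_interaction`.
#' @export
analyte_spline_spec <- function(analyte = names(FBC_ANALYTES)) {
  analyte <- match.arg(analyte)
  list(
    analyte = analyte,
    age_knots = switch(analyte, HB = c(60, 70, 80), MCV = 55, PLT = 60),
    time_knots = 3,
    age_time_interaction = identical(analyte, "HB")
  )
}

# Fixed-effect design matrix shared by fitting, population-mean prediction
# and BLUP residual computation. Column names are stable so serialized
# coefficient vectors can be matched by name.
longitudinal_design <- function(age, time, spec) {
  ab <- linear_spline_basis(age, spec$age_knots)
  tb <- linear_spline_basis(time, spec$time_knots)
  colnames(ab) <- sub("^x", "age", colnames(ab))
  colnames(tb) <- sub("^x", "time", colnames(tb))
  X <- cbind(`(Intercept)` = 1, ab, tb)
  if (isTRUE(spec$age_time_interaction)) {
    X <- cbind(X, age_time = age * time)
  }
  X
}
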