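# half-up rounding to `digits` decimal places (printed diagnostic-accuracy
# tables use conventional rounding, not banker's)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Risk cut-off at a percentile of the predicted-risk distribution
#'
#' Empirical quantile by the inverse-ECDF (type-1) definition; a patient is
#' "flagged" when their risk is strictly above the cut-off, so under distinct
#' risks the flagged fraction equals `100 - percentile` percent.
#'
#' @param risks predicted risks (non-empty).
#' @param percentile value in \[0, 100\].
#' @return risk cut-off.
#' @export
percentile_threshold <- function(risks, percentile) {
  if (!length(risks)) stop("risks must be non-empty")
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  unname(quantile(risks, percentile / 100, type = 1, names = FALSE))
}

#' Confusion counts at a risk cut-off
#'
#' Cross-tabulates the flag `risk > cutoff` against a binary outcome (cases
#' diagnosed within the horizon = 1; censored patients count as non-events,
#' which makes the four counts sum to the full cohort size).
#'
#' @param risks predicted risks.
#' @param outcomes binary 0/1 outcome vector of the same length.
#' @param cutoff risk cut-off.
#' @return list with integer `tp`, `fp`, `tn`, `fn` and the `cutoff`.
#' @export
confusion_at_threshold <- function(risks, outcomes, cutoff) {
  if (length(risks) != length(outcomes)) stop("risks/outcomes length mismatch")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
  flag <- risks > cutoff
  list(tp = sum(flag & outcomes == 1), fp = sum(flag & outcomes == 0),
       tn = sum(!flag & outcomes == 0), fn = sum(!flag & outcomes == 1),
       cutoff = cutoff)
}

#' Diagnostic accuracy measures from confusion counts
#'
#' Sensitivity, specificity, PPV and NPV as percentages rounded half-up to
#' two decimal places; a measure whose denominator is zero is reported as
#' `NA`.
#'
#' @param cc confusion counts (list or data-frame row with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
accuracy_measures <- function(cc) {
  with(cc, {
    if (tp + fp + tn + fn == 0) stop("all confusion counts are zero")
    ratio <- function(num, den) if (den > 0) round_half_up(100 * num / den, 2) else NA_real_
    c(sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn))
  })
}

#' ROC curve over all distinct thresholds
#'
#' Sweeps every distinct predicted risk as a strictly-greater-than threshold
#' and reports (FPR, TPR) pairs plus the trapezoidal area, which equals the
#' Mann-Whitney statistic (tied predictions scoring one half).
#'
#' @param risks predicted risks.
#' @param outcomes binary 0/1 outcomes; both classes must be present.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(risks, outcomes) {
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  thr <- sort(unique(risks), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(risks >= t & outcomes == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(risks >= t & outcomes == 0) / n0, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Percentile-threshold diagnostic accuracy table
#'
#' One row per risk percentile: the risk cut-off, the four confusion counts
#' and the accuracy measures -- the layout of a published threshold table.
#'
#' @param risks predicted risks.
#' @param outcomes binary 0/1 outcomes.
#' @param percentiles risk percentiles to evaluate (75th-99th by default).
#' @return data frame with columns `percentile`, `cutoff`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
threshold_table <- function(risks, outcomes,
                            percentiles = c(75, 80, 85, 90, 95, 99)) {
  rows <- lapply(percentiles, function(p) {
    cut <- percentile_threshold(risks, p)
    cc <- confusion_at_threshold(risks, outcomes, cut)
    acc <- accuracy_measures(cc)
    data.frame(percentile = p, cutoff = cut, tp = cc$tp, fp = cc$fp,
               tn = cc$tn, fn = cc$fn, sensitivity = acc["sensitivity"],
               specificity = acc["specificity"], ppv = acc["ppv"],
               npv = acc["npv"], row.names = NULL)
  })
  do.call(rbind, rows)
}
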