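# ROC analysis for DVH indices: curve construction under the rule
# "predict ORN if index >= threshold", optimal operating point nearest
# (FPR 0, TPR 1), and the bootstrap-wrapped critical-volume derivation.

#' ROC curve for an exceedance classifier
#'
#' Thresholds are the distinct observed index values plus a `+Inf`
#' sentinel; a patient is called positive when their value is >= the
#' threshold (larger irradiated volume predicts ORN).  The AUC is the
#' trapezoidal area under the (FPR, TPR) polyline, which equals the
#' Mann-Whitney concordance U/(n1*n0) with ties counted 1/2.
#'
#' @param values per-patient index values.
#' @param labels logical (or 0/1) ORN outcomes; both classes required.
#' @return class `roc_curve`: `thresholds` (ascending), `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_curve <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels) || anyNA(values) || anyNA(labels))
    stop("'values' and 'labels' must be equal-length and complete",
         call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present", call. = FALSE)
  thr <- c(sort(unique(values)), Inf)
  # counts of cases/controls at each distinct value, accumulated from above
  pos_ge <- rev(cumsum(rev(tabulate(match(values[labels], thr),
                                    nbins = length(thr)))))
  neg_ge <- rev(cumsum(rev(tabulate(match(values[!labels], thr),
                                    nbins = length(thr)))))
  tpr <- pos_ge / n1
  fpr <- neg_ge / n0
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Optimal operating point of an ROC curve
#'
#' The threshold minimizing the Euclidean distance
#' sqrt((1 - TPR)^2 + FPR^2) to the ideal point (TPR 1, FPR 0).  Distance
#' ties are broken by the smaller FPR, then the larger threshold (the
#' more specific constraint).
#'
#' @param curve a `roc_curve`.
#' @return list with `critical_value`, `tpr`, `fpr`, `distance`.
#' @export
optimal_operating_point <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  d <- sqrt((1 - curve$tpr)^2 + curve$fpr^2)
  # lexicographic minimum over (distance, fpr, -threshold)
  best <- order(d, curve$fpr, -curve$thresholds)[1]
  list(critical_value = curve$thresholds[best], tpr = curve$tpr[best],
       fpr = curve$fpr[best], distance = d[best])
}

#' Derive a critical volume (dose-volume constraint) with bootstrap CI
#'
#' Point estimate: ROC optimal operating point on the full sample.
#' Uncertainty: percentile bootstrap over outcome-stratified resamples
#' (event count preserved) of the critical value and the AUC.
#'
#' @param values per-patient index values (one modality).
#' @param labels ORN outcomes.
#' @param spec a [bootstrap_spec()]; stratification here is by outcome.
#' @param index_name label for reporting (e.g. `"v40"`).
#' @return class `critical_volume_result`: `index_name`,
#'   `critical_value`, `tpr_at`, `fpr_at`, `auc`, `ci_low`, `ci_high`,
#'   `auc_ci`, `n_rejected`.
#' @export
critical_volume <- function(values, labels, spec = bootstrap_spec(),
                            index_name = "index") {
  labels <- as.logical(labels)
  curve <- roc_curve(values, labels)
  oop <- optimal_operating_point(curve)
  dat <- data.frame(values = values, orn = labels)
  bt <- bootstrap_ci(function(d) {
    cv <- roc_curve(d$values, d$orn)
    c(critical = optimal_operating_point(cv)$critical_value, auc = cv$auc)
  }, dat, spec, strata = labels)
  structure(list(index_name = index_name,
                 critical_value = oop$critical_value,
                 tpr_at = oop$tpr, fpr_at = oop$fpr, auc = curve$auc,
                 ci_low = bt$ci_low[["critical"]],
                 ci_high = bt$ci_high[["critical"]],
                 auc_ci = c(bt$ci_low[["auc"]], bt$ci_high[["auc"]]),
                 n_rejected = bt$n_rejected),
            class = "critical_volume_result")
}

#' @export
print.critical_volume_result <- function(x, ...) {
  cat(sprintf("%s: critical volume %.2f (95%% CI %.2f-%.2f), AUC %.3f (%.3f-%.3f), TPR %.3f, FPR %.3f\n",
              x$index_name, x$critical_value, x$ci_low, x$ci_high,
              x$auc, x$auc_ci[1], x$auc_ci[2], x$tpr_at, x$fpr_at))
  invisible(x)
}
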