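# Volume tolerance curves, photon equivalent constraint doses, and
# empirical RBE with joint bootstrap confidence intervals.

# Pool-adjacent-violators projection onto non-increasing sequences
# (equal weights).
.pava_nonincreasing <- function(v) {
  n <- length(v)
  vals <- v
  wts <- rep(1, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- v[i]; wts[m] <- 1
    while (m > 1L && vals[m - 1L] < vals[m]) {
      pooled <- (vals[m - 1L] * wts[m - 1L] + vals[m] * wts[m]) /
        (wts[m - 1L] + wts[m])
      wts[m - 1L] <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- pooled
      m <- m - 1L
    }
  }
  rep(vals[seq_len(m)], wts[seq_len(m)])
}

#' Build a volume tolerance curve from critical-volume results
#'
#' Assembles (dose level, critical volume) points in dose order.  A
#' physically sensible tolerance curve is non-increasing in dose;
#' violations (which arise in noisy bootstrap resamples) are repaired by
#' isotonic pool-adjacent-violators projection and flagged.
#'
#' @param critical_results list of `critical_volume_result`s, or a
#'   numeric vector of critical volumes.
#' @param dose_levels nominal dose levels (Gy[RBE]); taken from the
#'   result names `v<level>` when omitted.
#' @param modality `"photon"` or `"proton"` (annotation only).
#' @return class `tolerance_curve`: `data.frame` `dose`, `volume`, with
#'   attributes `modality` and `repaired`.
#' @export
build_tolerance_curve <- function(critical_results, dose_levels = NULL,
                                  modality = c("photon", "proton")) {
  modality <- match.arg(modality)
  if (is.list(critical_results) &&
      all(vapply(critical_results, inherits, logical(1),
                 "critical_volume_result"))) {
    vols <- vapply(critical_results, `[[`, numeric(1), "critical_value")
    if (is.null(dose_levels))
      dose_levels <- as.numeric(sub("^v", "", vapply(critical_results,
                                                     `[[`, character(1),
                                                     "index_name")))
  } else {
    vols <- as.numeric(critical_results)
    if (is.null(dose_levels)) dose_levels <- as.numeric(names(critical_results))
  }
  if (length(vols) < 2 || any(!is.finite(vols)) || any(is.na(dose_levels)))
    stop("need at least 2 dose levels with defined (finite) critical volumes",
         call. = FALSE)
  ord <- order(dose_levels)
  dose_levels <- dose_levels[ord]; vols <- vols[ord]
  if (any(duplicated(dose_levels)))
    stop("dose levels must be distinct", call. = FALSE)
  repaired <- FALSE
  if (is.unsorted(rev(vols))) {  # any increase with dose
    vols <- .pava_nonincreasing(vols)
    repaired <- TRUE
  }
  out <- data.frame(dose = dose_levels, volume = vols)
  attr(out, "modality") <- modality
  attr(out, "repaired") <- repaired
  class(out) <- c("tolerance_curve", "data.frame")
  out
}

#' Photon equivalent constraint dose for a target critical volume
#'
#' Inverts the photon tolerance curve by piecewise-linear interpolation
#' of dose as a function of critical volume.  Exact node hits return the
#' node dose (the lowest-dose node on a flat repaired segment).  Targets
#' outside the curve's volume range are linearly extrapolated from the
#' nearest segment and flagged.
#'
#' @param photon_curve a `tolerance_curve` (non-increasing volumes).
#' @param target_volume target critical volume, cc (> 0).
#' @return list with `dose` (Gy[RBE=1.0]) and `extrapolated`.
#' @export
equivalent_constraint_dose <- function(photon_curve, target_volume) {
  stopifnot(inherits(photon_curve, "tolerance_curve"))
  if (!is.numeric(target_volume) || length(target_volume) != 1L ||
      target_volume <= 0)
    stop("'target_volume' must be a positive scalar", call. = FALSE)
  d <- photon_curve$dose; v <- photon_curve$volume
  if (is.unsorted(rev(v)))
    stop("photon curve must be non-increasing in volume (repair upstream)",
         call. = FALSE)
  hit <- which(v == target_volume)
  if (length(hit)) return(list(dose = d[hit[1]], extrapolated = FALSE))
  n <- length(d)
  slopes <- which(v[-n] > v[-1])  # non-flat segments
  if (target_volume > v[1]) {
    # degenerate all-flat curve (pathological resample): clamp to the end
    if (!length(slopes)) return(list(dose = d[1], extrapolated = TRUE))
    seg <- slopes[1]
    extrapolated <- TRUE
  } else if (target_volume < v[n]) {
    if (!length(slopes)) return(list(dose = d[n], extrapolated = TRUE))
    seg <- slopes[length(slopes)]
    extrapolated <- TRUE
  } else {
    seg <- max(which(v > target_volume))
    extrapolated <- FALSE
  }
  dose <- d[seg] + (d[seg + 1L] - d[seg]) *
    (v[seg] - target_volume) / (v[seg] - v[seg + 1L])
  list(dose = dose, extrapolated = extrapolated)
}

#' Empirical RBE from an equivalent constraint dose
#'
#' Proton physical dose is nominal Gy[RBE=1.1] divided by 1.1; the
#' empirical RBE is the photon equivalent constraint dose divided by the
#' proton physical dose.
#'
#' @param proton_nominal_dose nominal proton dose, Gy[RBE=1.1] (> 0).
#' @param equivalent_dose photon equivalent constraint dose, Gy[RBE=1.0]
#'   (> 0).
#' @param extrapolated whether the equivalent dose was extrapolated.
#' @return class `rbe_estimate`: `proton_nominal_dose`,
#'   `proton_physical_dose`, `equivalent_constraint_dose`, `rbe`,
#'   `extrapolated`.
#' @export
empirical_rbe <- function(proton_nominal_dose, equivalent_dose,
                          extrapolated = FALSE) {
  if (proton_nominal_dose <= 0 || equivalent_dose <= 0)
    stop("doses must be positive", call. = FALSE)
  physical <- proton_nominal_dose / 1.1
  structure(list(proton_nominal_dose = proton_nominal_dose,
                 proton_physical_dose = physical,
                 equivalent_constraint_dose = equivalent_dose,
                 rbe = equivalent_dose / physical,
                 extrapolated = extrapolated),
            class = "rbe_estimate")
}

# Critical volumes at each level for one modality's index table; returns
# named vector over dose levels.
.critical_volumes_at <- function(index_table, dose_levels) {
  vapply(dose_levels, function(L) {
    v <- index_table[[paste0("v", L)]]
    optimal_operating_point(roc_curve(v, index_table$orn))$critical_value
  }, numeric(1))
}

# One full RBE derivation from an index table: critical volumes ->
# tolerance curves (isotonic repair) -> equivalent doses -> RBEs.  The
# photon curve may carry extra dose levels so that equivalent doses above
# the highest shared level are interpolated from data, not extrapolated.
.rbe_statistic <- function(index_table, dose_levels,
                           photon_levels = dose_levels) {
  ph <- index_table[index_table$modality == "photon", ]
  pr <- index_table[index_table$modality == "proton", ]
  cv_ph <- .critical_volumes_at(ph, photon_levels)
  cv_pr <- .critical_volumes_at(pr, dose_levels)
  # an index with no discriminative signal can yield the +Inf sentinel as
  # its operating point; such levels define no volume constraint
  keep <- is.finite(cv_ph)
  if (sum(keep) < 2)
    return(c(setNames(rep(NA_real_, 4 * length(dose_levels)),
                      c(paste0("rbe_", dose_levels),
                        paste0("eqdose_", dose_levels),
                        paste0("cv_photon_", dose_levels),
                        paste0("cv_proton_", dose_levels))),
             extrapolated = NA_real_, repaired = NA_real_))
  curve_ph <- build_tolerance_curve(cv_ph[keep], photon_levels[keep],
                                    "photon")
  curve_pr <- build_tolerance_curve(ifelse(is.finite(cv_pr), cv_pr,
                                           NA_real_)[is.finite(cv_pr)],
                                    dose_levels[is.finite(cv_pr)], "proton")
  eq_dose <- rep(NA_real_, length(dose_levels))
  extrap <- FALSE
  cv_pr_out <- rep(NA_real_, length(dose_levels))
  ok <- is.finite(cv_pr)
  cv_pr_out[ok] <- curve_pr$volume[match(dose_levels[ok], curve_pr$dose)]
  for (k in which(ok)) {
    e <- equivalent_constraint_dose(curve_ph, cv_pr_out[k])
    eq_dose[k] <- e$dose
    extrap <- extrap || e$extrapolated
  }
  rbe <- eq_dose / (dose_levels / 1.1)
  c(setNames(rbe, paste0("rbe_", dose_levels)),
    setNames(eq_dose, paste0("eqdose_", dose_levels)),
    setNames(cv_ph[match(dose_levels, photon_levels)],
             paste0("cv_photon_", dose_levels)),
    setNames(cv_pr_out, paste0("cv_proton_", dose_levels)),
    extrapolated = as.numeric(extrap),
    repaired = as.numeric(attr(curve_ph, "repaired") ||
                            attr(curve_pr, "repaired")))
}

#' Empirical RBE at each dose level with joint bootstrap CIs
#'
#' Point estimates from the full matched-cohort index table; uncertainty
#' from resampling patients within modality x outcome strata and
#' re-deriving, per resample, both modalities' critical volumes at every
#' dose level, the (isotonically repaired) tolerance curves, the photon
#' equivalent constraint doses at the proton critical volumes, and the
#' RBEs.  95% percentile intervals.
#'
#' @param index_table matched-cohort index table from
#'   [dvh_index_table()] (columns `modality`, `orn`, `v<level>`).
#' @param dose_levels nominal proton dose levels, Gy[RBE=1.1]; default
#'   c(40, 50, 60).
#' @param photon_levels dose levels for the photon tolerance curve; a
#'   superset of `dose_levels` (e.g. adding 70 and 75) lets equivalent
#'   doses above the highest shared level be interpolated from data
#'   instead of extrapolated.  Default: `dose_levels`.
#' @param spec a [bootstrap_spec()].
#' @return class `rbe_estimates`: `data.frame` with one row per dose
#'   level (`nominal_dose`, `physical_dose`, `cv_photon`, `cv_proton`,
#'   `equivalent_dose`, `eq_ci_low`, `eq_ci_high`, `rbe`, `rbe_ci_low`,
#'   `rbe_ci_high`, `extrapolated`), with attributes
#'   `extrapolation_rate`, `repair_rate`, `n_rejected`.
#' @export
rbe_with_ci <- function(index_table, dose_levels = c(40, 50, 60),
                        photon_levels = dose_levels,
                        spec = bootstrap_spec()) {
  if (!all(dose_levels %in% photon_levels))
    stop("'photon_levels' must contain every entry of 'dose_levels'",
         call. = FALSE)
  need <- unique(paste0("v", c(dose_levels, photon_levels)))
  if (!all(c("modality", "orn", need) %in% names(index_table)))
    stop("index_table must contain columns modality, orn and ",
         paste(need, collapse = ", "), call. = FALSE)
  for (m in c("photon", "proton")) {
    sub <- index_table[index_table$modality == m, ]
    if (nrow(sub) == 0L || sum(sub$orn) == 0L)
      stop(sprintf("no ORN cases among %s patients; RBE underivable", m),
           call. = FALSE)
  }
  bt <- bootstrap_ci(function(d) .rbe_statistic(d, dose_levels,
                                                 photon_levels),
                     index_table, spec)
  pt <- bt$point
  nm_rbe <- paste0("rbe_", dose_levels)
  nm_eq <- paste0("eqdose_", dose_levels)
  out <- data.frame(
    nominal_dose = dose_levels,
    physical_dose = dose_levels / 1.1,
    cv_photon = unname(pt[paste0("cv_photon_", dose_levels)]),
    cv_proton = unname(pt[paste0("cv_proton_", dose_levels)]),
    equivalent_dose = unname(pt[nm_eq]),
    eq_ci_low = unname(bt$ci_low[nm_eq]),
    eq_ci_high = unname(bt$ci_high[nm_eq]),
    rbe = unname(pt[nm_rbe]),
    rbe_ci_low = unname(bt$ci_low[nm_rbe]),
    rbe_ci_high = unname(bt$ci_high[nm_rbe]),
    extrapolated = as.logical(pt[["extrapolated"]]))
  attr(out, "extrapolation_rate") <- mean(bt$reps[, "extrapolated"])
  attr(out, "repair_rate") <- mean(bt$reps[, "repaired"])
  attr(out, "n_rejected") <- bt$n_rejected
  class(out) <- c("rbe_estimates", "data.frame")
  out
}

#' @export
print.rbe_estimates <- function(x, ...) {
  cat("Empirical RBE estimates (percentile bootstrap 95% CI)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %g Gy[RBE=1.1]: equivalent dose %.2f (%.2f-%.2f) Gy, RBE %.3f (%.3f-%.3f)%s\n",
      x$nominal_dose[i], x$equivalent_dose[i], x$eq_ci_low[i],
      x$eq_ci_high[i], x$rbe[i], x$rbe_ci_low[i], x$rbe_ci_high[i],
      if (x$extrapolated[i]) " [extrapolated]" else ""))
  }
  invisible(x)
}
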