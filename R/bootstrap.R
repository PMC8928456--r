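# Stratified percentile bootstrap.  Resamples rows with replacement
# within strata (group sizes preserved); resamples violating the
# minimum-event floor are redrawn and counted.

.strata_of <- function(data, spec) {
  if (!is.null(data$modality) && !is.null(data$orn) &&
      spec$stratification == "modality_outcome")
    return(interaction(data$modality, data$orn, drop = TRUE))
  if (!is.null(data$modality)) return(factor(data$modality))
  factor(rep("all", nrow(data)))
}

#' Percentile bootstrap confidence interval
#'
#' Draws `spec$n_reps` stratified resamples of the rows of `data` and
#' returns the 2.5/97.5 percentile bounds of `statistic_fn` (which may be
#' vector-valued) along with its full-sample point estimate.  Resamples
#' in which either modality retains fewer than `spec$min_cases` ORN cases
#' are redrawn and counted in `n_rejected`; if rejections exceed half of
#' all draws the procedure aborts.  Deterministic given `spec$seed`.
#'
#' @param statistic_fn function of a resampled `data` returning a numeric
#'   scalar or vector (constant names/length across resamples).
#' @param data a `data.frame` of per-patient rows; columns `modality` and
#'   `orn`, when present, define the strata and the rejection rule.
#' @param spec a [bootstrap_spec()].
#' @param strata optional explicit stratum factor overriding the spec's
#'   stratification.
#' @return list with `point`, `ci_low`, `ci_high`, `n_rejected`, `reps`
#'   (matrix of resample statistics, reps x components).
#' @export
bootstrap_ci <- function(statistic_fn, data, spec = bootstrap_spec(),
                         strata = NULL) {
  stopifnot(inherits(spec, "bootstrap_spec"), is.data.frame(data))
  if (is.null(strata)) strata <- .strata_of(data, spec)
  strata <- factor(strata)
  idx_by_stratum <- split(seq_len(nrow(data)), strata)
  point <- statistic_fn(data)
  set.seed(spec$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  check_events <- !is.null(data$modality) && !is.null(data$orn)
  n_rejected <- 0L
  accepted <- 0L
  reps <- matrix(NA_real_, nrow = spec$n_reps, ncol = length(point))
  colnames(reps) <- names(point)
  while (accepted < spec$n_reps) {
    take <- unlist(lapply(idx_by_stratum, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    d <- data[take, , drop = FALSE]
    if (check_events) {
      ev <- tapply(d$orn, d$modality, sum)
      if (any(is.na(ev)) || any(ev < spec$min_cases)) {
        n_rejected <- n_rejected + 1L
        if (n_rejected > spec$n_reps && n_rejected > accepted)
          stop("bootstrap resample rejection rate exceeds 50%; ",
               "too few ORN cases to resample stably", call. = FALSE)
        next
      }
    }
    accepted <- accepted + 1L
    reps[accepted, ] <- statistic_fn(d)
  }
  ci <- apply(reps, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              names = FALSE)
  list(point = point, ci_low = setNames(ci[1, ], names(point)),
       ci_high = setNames(ci[2, ], names(point)),
       n_rejected = n_rejected, reps = reps)
}
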