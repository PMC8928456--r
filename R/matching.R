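# Propensity-score estimation and 1:1 greedy nearest-neighbor matching of
# photon controls to proton patients, without replacement, plus covariate
# balance diagnostics.

.default_terms <- c("gender", "stage", "chemo", "hypertension", "diabetes",
                    "dental_extraction", "current_smoker", "smoking_history")

#' Fit a propensity model for proton treatment assignment
#'
#' Maximum-likelihood logistic regression of proton-vs-photon modality on
#' main effects of the requested covariates, by Newton-Raphson (IRLS) from
#' a zero start.  Convergence when the largest coefficient change is below
#' 1e-8, capped at 100 iterations.  Under (quasi-)separation the fit is
#' flagged non-converged with a warning and scores are clipped to
#' [1e-12, 1-1e-12].
#'
#' @param records cohort record table (see [generate_cohort()]).
#' @param covariate_terms character vector of covariate column names;
#'   default: the eight matching factors (gender, stage, chemotherapy,
#'   hypertension, diabetes, dental extraction, current smoker, smoking
#'   history).  Age and prescription dose are deliberately not part of the
#'   model but appear in balance diagnostics.
#' @return class `propensity_fit`: `coefficients`, `scores` (named by
#'   patient id), `converged`, `iterations`.
#' @export
fit_propensity <- function(records, covariate_terms = .default_terms) {
  if (!all(covariate_terms %in% names(records)))
    stop("unknown covariate terms: ",
         paste(setdiff(covariate_terms, names(records)), collapse = ", "),
         call. = FALSE)
  y <- as.numeric(records$modality == "proton")
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least 2 patients in each modality", call. = FALSE)
  df <- records[, covariate_terms, drop = FALSE]
  for (cl in names(df)) if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  # constant covariates carry no information and break the factor contrasts
  constant <- vapply(df, function(x) length(unique(x)) < 2, logical(1))
  df <- df[, !constant, drop = FALSE]
  X <- if (ncol(df)) stats::model.matrix(~ ., data = df)
       else matrix(1, nrow(records), 1, dimnames = list(NULL, "(Intercept)"))

  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(XtWX, score), error = function(e)
      solve(XtWX + diag(1e-10, ncol(X)), score))
    beta_new <- beta + drop(step)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-8) { converged <- TRUE; break }
    if (iter >= 100L) break
  }
  if (!converged || any(abs(beta) > 30))
    warning("propensity fit did not converge (possible separation); scores clipped",
            call. = FALSE)
  if (any(abs(beta) > 30)) converged <- FALSE
  scores <- pmin(pmax(plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
  names(scores) <- records$patient_id
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 scores = scores, converged = converged,
                 iterations = iter),
            class = "propensity_fit")
}

#' Greedy 1:1 nearest-neighbor propensity matching without replacement
#'
#' Proton (treated) patients are processed in descending propensity order;
#' each takes the still-unused photon patient with the closest score.
#' Ties in score distance are broken by the smaller photon identifier (in
#' sort order); ties in the processing order by the smaller proton
#' identifier.  Deterministic, and invariant to photon-pool input order.
#'
#' @param fit a `propensity_fit`.
#' @param records the record table the fit was computed on.
#' @return class `matched_cohort`: `pairs` (`proton_id`, `photon_id`,
#'   `score_proton`, `score_photon`), `unmatched_proton`, `match_order`.
#' @export
greedy_match <- function(fit, records) {
  stopifnot(inherits(fit, "propensity_fit"))
  scores <- fit$scores[records$patient_id]
  is_p <- records$modality == "proton"
  proton_ids <- records$patient_id[is_p]
  photon_ids <- records$patient_id[!is_p]
  if (length(photon_ids) < length(proton_ids))
    warning("photon pool smaller than proton pool; some proton patients unmatched",
            call. = FALSE)
  ord <- order(-scores[proton_ids], proton_ids)
  proton_ids <- proton_ids[ord]
  # photon pool in id sort order so which.min's first-hit is the tie-break
  photon_ids <- photon_ids[order(photon_ids)]
  g_scores <- scores[photon_ids]
  used <- rep(FALSE, length(photon_ids))
  pairs <- vector("list", length(proton_ids))
  unmatched <- character(0)
  for (k in seq_along(proton_ids)) {
    if (all(used)) { unmatched <- c(unmatched, proton_ids[k]); next }
    d <- abs(g_scores - scores[proton_ids[k]])
    d[used] <- Inf
    j <- which.min(d)
    used[j] <- TRUE
    pairs[[k]] <- data.frame(proton_id = proton_ids[k],
                             photon_id = photon_ids[j],
                             score_proton = unname(scores[proton_ids[k]]),
                             score_photon = unname(g_scores[j]),
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(proton_id = character(0), photon_id = character(0),
                        score_proton = numeric(0), score_photon = numeric(0))
  structure(list(pairs = pairs, unmatched_proton = unmatched,
                 match_order = proton_ids),
            class = "matched_cohort")
}

#' Restrict a record table to a matched cohort
#'
#' @param records record table.
#' @param matched a `matched_cohort` (or its `pairs` data.frame).
#' @return the subset of `records` in the matched pairs.
#' @export
matched_records <- function(records, matched) {
  pairs <- if (inherits(matched, "matched_cohort")) matched$pairs else matched
  records[records$patient_id %in% c(pairs$proton_id, pairs$photon_id), ,
          drop = FALSE]
}

.balance_p <- function(records, covariate) {
  if (covariate %in% c("age", "prescription_dose")) {
    x <- records[[covariate]][records$modality == "photon"]
    y <- records[[covariate]][records$modality == "proton"]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    t_test_two_sample(x, y)$p.value
  } else {
    tab <- table(records$modality, as.character(records[[covariate]]))
    if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
    chi_square(tab)$p.value
  }
}

#' Covariate balance before and after matching
#'
#' Two-sided p-values for photon-vs-proton covariate differences:
#' chi-square for categorical covariates, Welch t for age and prescription
#' dose; computed overall and within the ORN and control strata, before
#' (full cohort) and after (matched subset) matching.  Strata with a
#' degenerate contingency table report `NA`.
#'
#' @param records full cohort record table.
#' @param matched a `matched_cohort`.
#' @param covariates covariates to test.
#' @return a `data.frame`: `covariate`, `stratum`, `p_pre`, `p_post`.
#' @export
balance_table <- function(records, matched,
                          covariates = c(.default_terms, "age",
                                         "prescription_dose")) {
  post <- matched_records(records, matched)
  strata <- list(overall = function(r) r,
                 orn = function(r) r[r$orn, , drop = FALSE],
                 control = function(r) r[!r$orn, , drop = FALSE])
  rows <- list()
  for (cv in covariates) for (st in names(strata)) {
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, stratum = st,
      p_pre = .balance_p(strata[[st]](records), cv),
      p_post = .balance_p(strata[[st]](post), cv),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
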