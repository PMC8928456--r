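# End-to-end orchestration: generate (or load) a cohort, match, compute
# DVH indices, test index significance, derive DVCs and empirical RBEs,
# and render a run report as delimited text + JSON.

#' ORN incidence summary per modality
#'
#' Crude incidence (all patients) and site-restricted incidence (primary
#' within the oral cavity or oropharynx), with numerators and
#' denominators retained.  `pct` is 100 x proportion, unrounded; the
#' print method shows 1 decimal place for crude and 2 for site-restricted
#' rates.
#'
#' @param records cohort record table.
#' @return class `incidence_summary`: `data.frame` with `modality`,
#'   `scope`, `events`, `n`, `pct`, `undefined`.
#' @export
incidence_summary <- function(records) {
  stopifnot(all(c("modality", "orn", "oropharynx_or_oral_cavity") %in%
                  names(records)))
  rows <- list()
  for (m in c("photon", "proton", "all")) {
    r <- if (m == "all") records else records[records$modality == m, ]
    for (scope in c("crude", "site_restricted")) {
      rr <- if (scope == "crude") r else r[r$oropharynx_or_oral_cavity, ]
      n <- nrow(rr); ev <- sum(rr$orn)
      rows[[length(rows) + 1L]] <- data.frame(
        modality = m, scope = scope, events = ev, n = n,
        pct = if (n > 0) 100 * ev / n else NA_real_,
        undefined = n == 0, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("incidence_summary", "data.frame")
  out
}

#' @export
print.incidence_summary <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    dp <- if (x$scope[i] == "crude") 1 else 2
    cat(sprintf("%-7s %-15s %d/%d (%s%%)\n", x$modality[i], x$scope[i],
                x$events[i], x$n[i],
                if (x$undefined[i]) "undefined" else
                  formatC(round(x$pct[i], dp), format = "f", digits = dp)))
  }
  invisible(x)
}

# Table-1-analog: covariate counts and percentages by modality x outcome.
.cohort_summary <- function(records) {
  grp <- interaction(records$modality, ifelse(records$orn, "orn", "control"),
                     sep = "_")
  count_pct <- function(mask) {
    vapply(split(mask, grp), function(v)
      sprintf("%d (%.1f)", sum(v), 100 * mean(v)), character(1))
  }
  covs <- list(female = records$gender == "female",
               stage_I = records$stage == "I",
               stage_II = records$stage == "II",
               stage_III = records$stage == "III",
               stage_IV = records$stage == "IV",
               stage_X = records$stage == "X",
               chemo = records$chemo,
               hypertension = records$hypertension,
               diabetes = records$diabetes,
               dental_extraction = records$dental_extraction,
               smoking_history = records$smoking_history,
               current_smoker = records$current_smoker,
               oropharynx_or_oral_cavity = records$oropharynx_or_oral_cavity)
  tab <- do.call(rbind, lapply(covs, count_pct))
  data.frame(covariate = names(covs), tab, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param n cohort size for synthetic generation (ignored when
#'   `cohort_dir` is given).
#' @param seed master seed; the generator and the bootstrap derive their
#'   seeds from it.
#' @param dose_levels nominal dose levels for DVCs and RBE.
#' @param n_reps bootstrap repetitions.
#' @param cohort_dir optional directory with a persisted cohort (read
#'   instead of generating).
#' @param index_file optional precomputed DVH index table (CSV with
#'   columns `patient_id`, `modality`, `orn`, `v40`, ...); indices-only
#'   mode skips generation, dosimetry and matching.
#' @param out_dir optional output directory for report artifacts.
#' @param covariate_cfg,confounding_cfg,dose_cfg,outcome_cfg generator
#'   configs.
#' @return class `pipeline_config`.
#' @export
pipeline_config <- function(n = 1266L, seed = 1L,
                            dose_levels = c(40, 50, 60),
                            n_reps = 1000L,
                            cohort_dir = NULL, index_file = NULL,
                            out_dir = NULL,
                            covariate_cfg = covariate_config(),
                            confounding_cfg = confounding_config(),
                            dose_cfg = dose_field_config(),
                            outcome_cfg = outcome_config()) {
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 dose_levels = dose_levels, n_reps = as.integer(n_reps),
                 cohort_dir = cohort_dir, index_file = index_file,
                 out_dir = out_dir, covariate_cfg = covariate_cfg,
                 confounding_cfg = confounding_cfg, dose_cfg = dose_cfg,
                 outcome_cfg = outcome_cfg),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys `n`, `seed`, `dose_levels`, `n_reps`, `cohort_dir`,
#' `index_file`, `out_dir`, and nested `covariate`, `confounding`,
#' `dose_field`, `outcome` blocks whose entries are passed to the
#' corresponding config constructors.
#'
#' @param path YAML file path.
#' @return class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; accept `n_patients`
  # as the canonical key and repair a boolean-parsed `n`
  names(y)[names(y) == "FALSE"] <- "n"
  if (!is.null(y$n_patients)) { y$n <- y$n_patients; y$n_patients <- NULL }
  args <- y[intersect(names(y), c("n", "seed", "dose_levels", "n_reps",
                                  "cohort_dir", "index_file", "out_dir"))]
  if (!is.null(y$covariate))
    args$covariate_cfg <- do.call(covariate_config, y$covariate)
  if (!is.null(y$confounding)) {
    cf <- y$confounding
    if (!is.null(cf$modality_logit_coefficients))
      cf$modality_logit_coefficients <- unlist(cf$modality_logit_coefficients)
    args$confounding_cfg <- do.call(confounding_config, cf)
  }
  if (!is.null(y$dose_field))
    args$dose_cfg <- do.call(dose_field_config, y$dose_field)
  if (!is.null(y$outcome))
    args$outcome_cfg <- do.call(outcome_config, y$outcome)
  do.call(pipeline_config, args)
}

#' Run the full ORN-RBE pipeline
#'
#' Full-cohort mode: generate (or load) a cohort, compute per-patient
#' DVH indices, form the 1:1 propensity-matched cohort, test index
#' significance, derive per-modality critical volumes with bootstrap CIs,
#' and compute equivalent constraint doses and empirical RBEs.
#' Indices-only mode (`index_file` set): skip generation, dosimetry and
#' matching and run the statistical stages on the supplied table.
#' Deterministic given the config seed.  When `out_dir` is set, all
#' report components are written as CSV plus a JSON summary carrying
#' provenance (seed, config hash, package version).
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return class `orn_rbe_report`: list with `incidence`,
#'   `cohort_summary`, `balance`, `significance`, `critical_volumes`,
#'   `tolerance_curves`, `rbe`, `provenance` (components `NULL` where a
#'   mode skips them).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "setup"
  result <- tryCatch({
    spec <- bootstrap_spec(n_reps = config$n_reps,
                           seed = config$seed + 1000L)
    incidence <- NULL; cohort_summary <- NULL; balance <- NULL
    if (!is.null(config$index_file)) {
      stage <- "load-indices"
      midx <- read.csv(config$index_file, stringsAsFactors = FALSE)
      midx$orn <- midx$orn == 1 | midx$orn == TRUE
    } else {
      if (!is.null(config$cohort_dir)) {
        stage <- "load-cohort"
        cohort <- read_cohort(config$cohort_dir)
      } else {
        stage <- "generate"
        cohort <- generate_cohort(config$n,
                                  covariate_cfg = config$covariate_cfg,
                                  confounding_cfg = config$confounding_cfg,
                                  dose_cfg = config$dose_cfg,
                                  outcome_cfg = config$outcome_cfg,
                                  seed = config$seed)
      }
      stage <- "dosimetry"
      idx <- dvh_index_table(cohort)
      stage <- "matching"
      fit <- fit_propensity(cohort$records)
      matched <- greedy_match(fit, cohort$records)
      balance <- balance_table(cohort$records, matched)
      incidence <- incidence_summary(cohort$records)
      cohort_summary <- .cohort_summary(cohort$records)
      midx <- idx[idx$patient_id %in% c(matched$pairs$proton_id,
                                        matched$pairs$photon_id), ]
    }
    stage <- "significance"
    sig_indices <- intersect(c("v40", "v50", "v60", "v70", "v75",
                               "d001cc", "dmean"), names(midx))
    sig <- index_significance_table(midx, indices = sig_indices)
    stage <- "critical-volumes"
    cvs <- list()
    for (m in c("photon", "proton")) {
      sub <- midx[midx$modality == m, ]
      cvs[[m]] <- lapply(config$dose_levels, function(L)
        critical_volume(sub[[paste0("v", L)]], sub$orn,
                        spec = bootstrap_spec(config$n_reps,
                                              seed = config$seed + 2000L),
                        index_name = paste0("v", L)))
    }
    curves <- list(
      photon = build_tolerance_curve(cvs$photon, config$dose_levels,
                                     "photon"),
      proton = build_tolerance_curve(cvs$proton, config$dose_levels,
                                     "proton"))
    stage <- "rbe"
    rbe <- rbe_with_ci(midx, config$dose_levels, spec = spec)
    stage <- "report"
    provenance <- list(seed = config$seed,
                       n_reps = config$n_reps,
                       dose_levels = config$dose_levels,
                       package_version = as.character(
                         utils::packageVersion("ornrbe")),
                       config_hash = .config_hash(config),
                       timestamp_free = TRUE)
    report <- structure(list(incidence = incidence,
                             cohort_summary = cohort_summary,
                             balance = balance, significance = sig,
                             critical_volumes = cvs,
                             tolerance_curves = curves, rbe = rbe,
                             provenance = provenance),
                        class = "orn_rbe_report")
    if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
    report
  }, error = function(e) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(c(stage, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
    }
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

# Content hash of the configuration (md5 of its deparsed, path-free form).
.config_hash <- function(config) {
  x <- config[setdiff(names(config), c("cohort_dir", "index_file",
                                       "out_dir"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(report$incidence, "incidence.csv")
  wr(report$cohort_summary, "cohort_summary.csv")
  wr(report$balance, "balance.csv")
  wr(report$significance, "significance.csv")
  wr(as.data.frame(report$rbe), "rbe.csv")
  for (m in names(report$tolerance_curves))
    wr(as.data.frame(report$tolerance_curves[[m]]),
       sprintf("tolerance_curve_%s.csv", m))
  cv_rows <- do.call(rbind, lapply(names(report$critical_volumes),
    function(m) do.call(rbind, lapply(report$critical_volumes[[m]],
      function(r) data.frame(modality = m, index = r$index_name,
                             critical_value = r$critical_value,
                             ci_low = r$ci_low, ci_high = r$ci_high,
                             auc = r$auc, auc_ci_low = r$auc_ci[1],
                             auc_ci_high = r$auc_ci[2],
                             tpr = r$tpr_at, fpr = r$fpr_at)))))
  wr(cv_rows, "critical_volumes.csv")
  summary <- list(provenance = report$provenance,
                  rbe = as.data.frame(report$rbe),
                  critical_volumes = cv_rows)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.orn_rbe_report <- function(x, ...) {
  cat("ORN-RBE pipeline report\n")
  if (!is.null(x$incidence)) { cat("\nIncidence:\n"); print(x$incidence) }
  cat("\nIndex significance (matched cohort):\n")
  print(x$significance, row.names = FALSE)
  cat("\n")
  print(x$rbe)
  invisible(x)
}
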