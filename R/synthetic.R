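# Synthetic cohort generator: covariates, confounded modality assignment,
# parametric per-patient dose/LET fields, and a logistic ORN outcome driven
# by the photon-equivalent (biological) effective volume, with a known
# LET-linear ground-truth RBE.

# LET upper-envelope at nominal dose d (Gy[RBE=1.1]): linear between the
# configured 40- and 60-Gy edges, extended linearly, capped at 1.5x the
# 40-Gy edge (low-dose fringe) and floored at a small positive value.
.let_envelope <- function(dose, dose_cfg) {
  e40 <- dose_cfg$let_edge_at_40
  e60 <- dose_cfg$let_edge_at_60
  env <- e40 + (e60 - e40) * (dose - 40) / 20
  pmin(pmax(env, 0.2), 1.5 * e40)
}

#' Ground-truth effective RBE of a generator configuration
#'
#' The analytic effective RBE the generator implies at a nominal proton
#' dose: `true_rbe_intercept + true_rbe_slope * mean LET at that dose`.
#' LET is drawn uniformly below the dose-dependent envelope, so the mean
#' LET is half the envelope (LET noise is symmetric and its truncation at
#' zero is negligible at default settings).  Downstream recovery tests
#' compare pipeline RBE estimates against this value.
#'
#' @param nominal_dose nominal proton dose(s), Gy[RBE=1.1].
#' @param dose_cfg a [dose_field_config()].
#' @param outcome_cfg an [outcome_config()].
#' @return numeric vector of effective RBE values.
#' @export
true_effective_rbe <- function(nominal_dose,
                               dose_cfg = dose_field_config(),
                               outcome_cfg = outcome_config()) {
  mean_let <- .let_envelope(nominal_dose, dose_cfg) / 2
  outcome_cfg$true_rbe_intercept + outcome_cfg$true_rbe_slope * mean_let
}

# Sigmoid dose field for one patient sampled at equal-volume voxel centres.
.dose_field <- function(n_voxels, dmax, overlap, falloff, noise_sd) {
  u <- (seq_len(n_voxels) - 0.5) / n_voxels
  dose <- dmax * stats::plogis((overlap - u) / falloff)
  if (noise_sd > 0) dose <- dose + stats::rnorm(n_voxels, 0, noise_sd)
  pmax(dose, 0)
}

#' Generate a synthetic photon/proton cohort with dose-LET fields
#'
#' Produces `n_patients` patient records and matching mandible voxel
#' sample sets.  Modality is assigned by a logistic model on the
#' covariates (intercept calibrated to the target proton fraction), dose
#' fields are modality-specific sigmoid falloffs, proton LET is drawn
#' below a dose-decreasing envelope, and ORN is Bernoulli with logistic
#' probability in the effective volume V_eff (cc of biological dose >=
#' the reference threshold), where proton biological dose = physical dose
#' x RBE(LET) and physical dose = nominal/1.1.
#'
#' @param n_patients cohort size (>= 20).
#' @param covariate_cfg a [covariate_config()].
#' @param confounding_cfg a [confounding_config()].
#' @param dose_cfg a [dose_field_config()].
#' @param outcome_cfg an [outcome_config()].
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return an object of class `orn_cohort`: a list with `records` (one
#'   row per patient), `samples` (a long `data.table` of voxel samples:
#'   `patient_id`, `volume_cc`, `dose_gy_rbe`, `let_kev_um`), the four
#'   configs, and `risk_intercept_used` (post-calibration value).
#' @export
generate_cohort <- function(n_patients,
                            covariate_cfg = covariate_config(),
                            confounding_cfg = confounding_config(),
                            dose_cfg = dose_field_config(),
                            outcome_cfg = outcome_config(),
                            seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 20)
    stop("'n_patients' must be at least 20", call. = FALSE)
  n <- as.integer(n_patients)
  stopifnot(inherits(covariate_cfg, "covariate_config"),
            inherits(confounding_cfg, "confounding_config"),
            inherits(dose_cfg, "dose_field_config"),
            inherits(outcome_cfg, "outcome_config"))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  cc <- covariate_cfg
  id <- sprintf("P%05d", seq_len(n))
  gender <- ifelse(runif(n) < cc$prob_female, "female", "male")
  age <- round(pmin(pmax(rnorm(n, cc$age_mean, cc$age_sd),
                         cc$age_range[1]), cc$age_range[2]))
  stage <- sample(c("I", "II", "III", "IV", "X"), n, replace = TRUE,
                  prob = cc$stage_probs)
  chemo <- runif(n) < cc$prob_chemo
  hypertension <- runif(n) < cc$prob_hypertension
  diabetes <- runif(n) < cc$prob_diabetes
  dental_extraction <- runif(n) < cc$prob_extraction
  smoking_history <- runif(n) < cc$prob_smoking_history
  # current smokers are a subset of ever-smokers
  current_smoker <- smoking_history &
    (runif(n) < cc$prob_current_smoker / cc$prob_smoking_history)
  site <- runif(n) < cc$prob_site
  # long-tailed prescription distribution with median near the 60 Gy floor
  rx_lo <- cc$prescription_dose_range[1]
  rx_hi <- cc$prescription_dose_range[2]
  prescription_dose <- round(rx_lo + (rx_hi - rx_lo) * rbeta(n, 0.5, 3), 1)

  # --- modality assignment: logistic confounding, intercept calibrated ---
  co <- confounding_cfg$modality_logit_coefficients
  term <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
  eta <- numeric(n) +
    term("female") * (gender == "female") +
    term("stage_II") * (stage == "II") +
    term("stage_III") * (stage == "III") +
    term("stage_IV") * (stage == "IV") +
    term("stage_X") * (stage == "X") +
    term("chemo") * chemo +
    term("hypertension") * hypertension +
    term("diabetes") * diabetes +
    term("dental_extraction") * dental_extraction +
    term("smoking_history") * smoking_history +
    term("current_smoker") * current_smoker
  a <- uniroot(function(a) mean(plogis(a + eta)) -
                 confounding_cfg$target_proton_fraction,
               interval = c(-30, 30), tol = 1e-10)$root
  p_proton <- plogis(a + eta)
  if (any(p_proton <= 0 | p_proton >= 1))
    stop("confounding_config: assignment probabilities left (0,1)", call. = FALSE)
  modality <- ifelse(runif(n) < p_proton, "proton", "photon")

  # --- dose/LET fields ---
  dc <- dose_cfg
  nv <- dc$n_voxels
  total_volume <- runif(n, dc$mandible_volume_range[1], dc$mandible_volume_range[2])
  voxel_volume <- total_volume / nv
  is_proton <- modality == "proton"
  sh <- function(i) if (is_proton[i]) dc$proton_dvh_shape else dc$photon_dvh_shape
  dose_list <- vector("list", n)
  let_list <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sh(i)
    dmax <- prescription_dose[i] * s$dmax_frac * exp(rnorm(1, 0, 0.03))
    overlap <- min(max(rnorm(1, s$overlap, s$overlap_sd), 0.02), 0.95)
    falloff <- s$falloff * exp(rnorm(1, 0, 0.15))
    dose <- .dose_field(nv, dmax, overlap, falloff, dc$dose_noise_sd)
    dose_list[[i]] <- dose
    if (is_proton[i]) {
      env <- .let_envelope(dose, dc)
      let <- runif(nv, 0, env) + rnorm(nv, 0, dc$let_noise_sd)
      let_list[[i]] <- pmax(let, 0)
    } else {
      let_list[[i]] <- numeric(nv)
    }
  }
  samples <- data.table::data.table(
    patient_id = rep(id, each = nv),
    volume_cc = rep(voxel_volume, each = nv),
    dose_gy_rbe = unlist(dose_list, use.names = FALSE),
    let_kev_um = unlist(let_list, use.names = FALSE))

  # --- outcome: logistic on effective (photon-equivalent) volume ---
  oc <- outcome_cfg
  rbe_of_let <- function(l) oc$true_rbe_intercept + oc$true_rbe_slope * l
  v_eff <- numeric(n)
  for (i in seq_len(n)) {
    dose <- dose_list[[i]]
    bio <- if (is_proton[i]) (dose / 1.1) * rbe_of_let(let_list[[i]]) else dose
    v_eff[i] <- voxel_volume[i] * sum(bio >= oc$reference_threshold)
  }
  risk_intercept <- oc$risk_intercept
  if (!is.null(oc$target_incidence)) {
    risk_intercept <- uniroot(
      function(a) mean(plogis(a + oc$risk_slope * v_eff)) - oc$target_incidence,
      interval = c(-50, 50), tol = 1e-10)$root
  }
  p_orn <- plogis(risk_intercept + oc$risk_slope * v_eff)
  orn <- runif(n) < p_orn
  orn_grade <- rep(NA_integer_, n)
  if (any(orn))
    orn_grade[orn] <- sample(c(2L, 3L, 4L), sum(orn), replace = TRUE,
                             prob = oc$grade_probs)

  records <- data.frame(
    patient_id = id, modality = modality, age = age, gender = gender,
    stage = stage, prescription_dose = prescription_dose, chemo = chemo,
    hypertension = hypertension, diabetes = diabetes,
    dental_extraction = dental_extraction,
    smoking_history = smoking_history, current_smoker = current_smoker,
    oropharynx_or_oral_cavity = site, orn = orn, orn_grade = orn_grade,
    stringsAsFactors = FALSE)

  structure(list(records = records, samples = samples,
                 covariate_cfg = covariate_cfg,
                 confounding_cfg = confounding_cfg,
                 dose_cfg = dose_cfg, outcome_cfg = outcome_cfg,
                 risk_intercept_used = risk_intercept,
                 seed = as.integer(seed)),
            class = "orn_cohort")
}

#' @export
print.orn_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("orn_cohort: %d patients (%d photon, %d proton), %d ORN cases; seed %d\n",
              nrow(r), sum(r$modality == "photon"),
              sum(r$modality == "proton"), sum(r$orn), x$seed))
  invisible(x)
}

#' Extract one patient's voxel samples
#'
#' @param cohort an `orn_cohort` or a long samples `data.table`/`data.frame`.
#' @param id patient identifier.
#' @return a `data.frame` with columns `volume_cc`, `dose_gy_rbe`,
#'   `let_kev_um` for that patient.
#' @export
patient_samples <- function(cohort, id) {
  s <- if (inherits(cohort, "orn_cohort")) cohort$samples else cohort
  out <- as.data.frame(s[s$patient_id == id,
                         c("volume_cc", "dose_gy_rbe", "let_kev_um")])
  if (nrow(out) == 0L)
    stop(sprintf("no voxel samples for patient '%s'", id), call. = FALSE)
  out
}
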