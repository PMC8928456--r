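# Configuration objects for the synthetic cohort generator and the
# bootstrap engine.  Defaults encode the cohort the analysis assumes:
# covariate marginals of a 1,266-patient head-and-neck cohort (26.5%
# proton), modality confounding on tumor stage / hypertension / smoking
# history, photon vs proton mandible DVH shapes, and a proton LET envelope
# falling from ~7 to ~3.5 keV/um as dose rises 40 -> 60 Gy[RBE=1.1].

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("config parameter '%s' must be a probability in [0,1]", name),
         call. = FALSE)
  x
}

.check_range <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stop(sprintf("config parameter '%s' must be an ascending length-2 interval", name),
         call. = FALSE)
  if (x[1] < lo || x[2] > hi)
    stop(sprintf("config parameter '%s' must lie within [%g, %g]", name, lo, hi),
         call. = FALSE)
  x
}

#' Covariate configuration for the synthetic cohort
#'
#' Marginal distributions of the clinical covariates.  Defaults reproduce
#' the characteristics table of a 1,266-patient head-and-neck cohort:
#' 25.8% female, median age ~62, tumor stage mix I/II/III/IV/X =
#' 10.3/11.9/14.4/52.8/10.6%, 58% concurrent chemotherapy, 50.2%
#' hypertension, 14.3% diabetes, 16.3% dental extraction, 52.1% smoking
#' history, 10.7% current smokers, 54.5% oropharynx / oral-cavity primaries,
#' prescription doses 60-81 Gy[RBE] (median 60) at 120-220 cGy[RBE] per
#' fraction.
#'
#' @param prob_female probability of female gender.
#' @param age_mean,age_sd age distribution (years), truncated to `age_range`.
#' @param age_range allowed age interval (years).
#' @param stage_probs length-5 probability vector over stages I, II, III,
#'   IV, X; must sum to 1 (tolerance 1e-9).
#' @param prob_chemo,prob_hypertension,prob_diabetes,prob_extraction
#'   probabilities of concurrent chemotherapy, hypertension, diabetes and
#'   dental extraction.
#' @param prob_smoking_history,prob_current_smoker probabilities of any
#'   smoking history and of current smoking.  Current smokers are a subset
#'   of patients with smoking history.
#' @param prob_site probability that the primary is within the oral cavity
#'   or oropharynx (the site stratum used for site-restricted incidence).
#' @param prescription_dose_range prescription dose interval, Gy[RBE];
#'   lower bound must be >= 60.
#' @param fraction_size_range fraction size interval, cGy[RBE]; must lie
#'   within [120, 220].
#' @return an object of class `covariate_config`.
#' @export
covariate_config <- function(prob_female = 0.258,
                             age_mean = 61, age_sd = 13,
                             age_range = c(11, 93),
                             stage_probs = c(I = 0.103, II = 0.119,
                                             III = 0.144, IV = 0.528,
                                             X = 0.106),
                             prob_chemo = 0.580,
                             prob_hypertension = 0.502,
                             prob_diabetes = 0.143,
                             prob_extraction = 0.163,
                             prob_smoking_history = 0.521,
                             prob_current_smoker = 0.107,
                             prob_site = 0.545,
                             prescription_dose_range = c(60, 81),
                             fraction_size_range = c(120, 220)) {
  for (nm in c("prob_female", "prob_chemo", "prob_hypertension",
               "prob_diabetes", "prob_extraction", "prob_smoking_history",
               "prob_current_smoker", "prob_site"))
    .check_prob(get(nm), nm)
  if (length(stage_probs) != 5L || any(stage_probs < 0) ||
      abs(sum(stage_probs) - 1) > 1e-9)
    stop("config parameter 'stage_probs' must be a 5-vector summing to 1",
         call. = FALSE)
  if (prob_current_smoker > prob_smoking_history)
    stop("config parameter 'prob_current_smoker' cannot exceed 'prob_smoking_history'",
         call. = FALSE)
  .check_range(prescription_dose_range, "prescription_dose_range", lo = 60)
  .check_range(fraction_size_range, "fraction_size_range", lo = 120, hi = 220)
  .check_range(age_range, "age_range", lo = 0)
  if (age_sd <= 0) stop("config parameter 'age_sd' must be positive", call. = FALSE)
  names(stage_probs) <- c("I", "II", "III", "IV", "X")
  structure(list(prob_female = prob_female, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 stage_probs = stage_probs, prob_chemo = prob_chemo,
                 prob_hypertension = prob_hypertension,
                 prob_diabetes = prob_diabetes,
                 prob_extraction = prob_extraction,
                 prob_smoking_history = prob_smoking_history,
                 prob_current_smoker = prob_current_smoker,
                 prob_site = prob_site,
                 prescription_dose_range = prescription_dose_range,
                 fraction_size_range = fraction_size_range),
            class = "covariate_config")
}

#' Modality-confounding configuration
#'
#' Log-odds contributions of covariates to proton (vs photon) treatment
#' assignment.  The intercept is calibrated per cohort so the expected
#' proton fraction equals `target_proton_fraction`.  Defaults reproduce the
#' documented pre-matching imbalance: proton patients are less likely to be
#' stage IV, hypertensive, or (current/former) smokers, and more likely to
#' be stage X.  Coefficient names: `female`, `stage_II`, `stage_III`,
#' `stage_IV`, `stage_X`, `chemo`, `hypertension`, `diabetes`,
#' `dental_extraction`, `smoking_history`, `current_smoker`.
#'
#' @param modality_logit_coefficients named numeric vector of log-odds
#'   contributions to proton assignment.
#' @param target_proton_fraction expected proton fraction; default
#'   335/1266.
#' @return an object of class `confounding_config`.
#' @export
confounding_config <- function(
    modality_logit_coefficients = c(
      female = -0.20, stage_II = -0.16, stage_III = -0.63,
      stage_IV = -0.70, stage_X = 0.42, chemo = -0.18,
      hypertension = -0.61, diabetes = -0.12, dental_extraction = 0.26,
      smoking_history = -0.89, current_smoker = -1.12),
    target_proton_fraction = 335 / 1266) {
  .check_prob(target_proton_fraction, "target_proton_fraction")
  if (target_proton_fraction <= 0 || target_proton_fraction >= 1)
    stop("config parameter 'target_proton_fraction' must be in (0,1)",
         call. = FALSE)
  if (is.null(names(modality_logit_coefficients)) ||
      any(!is.finite(modality_logit_coefficients)))
    stop("config parameter 'modality_logit_coefficients' must be a named finite numeric vector",
         call. = FALSE)
  structure(list(modality_logit_coefficients = modality_logit_coefficients,
                 target_proton_fraction = target_proton_fraction),
            class = "confounding_config")
}

#' Dose-field configuration for the synthetic cohort
#'
#' Each patient's mandible dose is a 1-D parametric field: a near-target
#' plateau at `dmax_frac` x prescription dose with a sigmoid falloff
#' centred at normalized position `overlap` (the fraction of the mandible
#' overlapping the high-dose region) and width `falloff`, sampled into
#' `n_voxels` equal-volume voxels.  Proton fields fall off more steeply
#' and overlap less, reproducing the photon-vs-proton median V40/V50/V60
#' contrast (30.94/20.44/8.68 cc photon vs 15.25/9.25/2.12 cc proton).
#' Proton LET (keV/um) is drawn uniformly below an envelope that decreases
#' linearly in dose between `let_edge_at_40` and `let_edge_at_60`, with
#' Gaussian noise of sd `let_noise_sd`, truncated at 0.
#'
#' @param mandible_volume_range mandible volume interval, cc.
#' @param photon_dvh_shape,proton_dvh_shape lists with elements
#'   `dmax_frac` (plateau level as a fraction of prescription dose),
#'   `falloff` (sigmoid width, normalized position units), `overlap`
#'   (median falloff midpoint position) and `overlap_sd` (between-patient
#'   sd of the midpoint).
#' @param n_voxels equal-volume voxels per patient.
#' @param dose_noise_sd per-voxel Gaussian dose noise, Gy[RBE].
#' @param let_edge_at_40,let_edge_at_60 LET envelope (upper edge) at 40 and
#'   60 Gy[RBE=1.1]; must satisfy `let_edge_at_40 > let_edge_at_60 > 0`.
#' @param let_noise_sd LET noise sd, keV/um.
#' @return an object of class `dose_field_config`.
#' @export
dose_field_config <- function(
    mandible_volume_range = c(55, 95),
    photon_dvh_shape = list(dmax_frac = 1.06, falloff = 0.14,
                            overlap = 0.44, overlap_sd = 0.13),
    proton_dvh_shape = list(dmax_frac = 1.04, falloff = 0.075,
                            overlap = 0.225, overlap_sd = 0.15),
    n_voxels = 500L,
    dose_noise_sd = 1.0,
    let_edge_at_40 = 7.0,
    let_edge_at_60 = 3.5,
    let_noise_sd = 0.3) {
  .check_range(mandible_volume_range, "mandible_volume_range", lo = 1e-6)
  for (nm in c("photon_dvh_shape", "proton_dvh_shape")) {
    sh <- get(nm)
    need <- c("dmax_frac", "falloff", "overlap", "overlap_sd")
    if (!all(need %in% names(sh)))
      stop(sprintf("config parameter '%s' must contain %s", nm,
                   paste(need, collapse = ", ")), call. = FALSE)
    if (sh$falloff <= 0 || sh$dmax_frac <= 0 || sh$overlap_sd < 0)
      stop(sprintf("config parameter '%s' has non-positive shape values", nm),
           call. = FALSE)
  }
  if (proton_dvh_shape$falloff >= photon_dvh_shape$falloff)
    stop("config parameter 'proton_dvh_shape': proton falloff must be steeper (smaller width) than photon",
         call. = FALSE)
  if (n_voxels < 10)
    stop("config parameter 'n_voxels' must be at least 10", call. = FALSE)
  if (!(let_edge_at_40 > let_edge_at_60 && let_edge_at_60 > 0))
    stop("config parameter 'let_edge_at_40' must exceed 'let_edge_at_60' > 0",
         call. = FALSE)
  if (let_noise_sd < 0 || dose_noise_sd < 0)
    stop("config parameter 'let_noise_sd'/'dose_noise_sd' must be non-negative",
         call. = FALSE)
  structure(list(mandible_volume_range = mandible_volume_range,
                 photon_dvh_shape = photon_dvh_shape,
                 proton_dvh_shape = proton_dvh_shape,
                 n_voxels = as.integer(n_voxels),
                 dose_noise_sd = dose_noise_sd,
                 let_edge_at_40 = let_edge_at_40,
                 let_edge_at_60 = let_edge_at_60,
                 let_noise_sd = let_noise_sd),
            class = "dose_field_config")
}

#' Outcome (ORN) configuration for the synthetic cohort
#'
#' The generator's ground truth: proton RBE is linear in LET,
#' `RBE(l) = true_rbe_intercept + true_rbe_slope * l`, so each proton
#' voxel's biological (photon-equivalent) dose equals physical dose x
#' RBE(LET), with physical dose = nominal Gy[RBE=1.1] / 1.1.  Photon
#' voxels use biological dose = nominal dose.  ORN probability is
#' logistic in the effective volume V_eff, the absolute volume (cc) with
#' biological dose >= `reference_threshold`.  When `target_incidence` is
#' given, `risk_intercept` is calibrated per cohort so the expected
#' incidence matches it.  The default intercept 1.1 makes the LET-disabled
#' null (`true_rbe_slope = 0`) coincide with the fixed-RBE clinical
#' assumption, under which identical Gy[RBE] fields imply identical risk.
#'
#' @param true_rbe_intercept RBE as LET approaches 0 (dimensionless).
#' @param true_rbe_slope RBE increment per keV/um.
#' @param risk_intercept logistic intercept; ignored (recalibrated) when
#'   `target_incidence` is non-`NULL`.
#' @param risk_slope logistic slope per cc of effective volume.
#' @param reference_threshold biological dose threshold for V_eff, Gy.
#' @param target_incidence overall ORN incidence to calibrate to, or
#'   `NULL` to use `risk_intercept` as given.
#' @param grade_probs categorical distribution of ORN grade among cases,
#'   over grades 2, 3, 4.
#' @return an object of class `outcome_config`.
#' @export
outcome_config <- function(true_rbe_intercept = 1.1,
                           true_rbe_slope = 0.15,
                           risk_intercept = -6.5,
                           risk_slope = 0.14,
                           reference_threshold = 40,
                           target_incidence = 0.05,
                           grade_probs = c(`2` = 0.5, `3` = 0.35, `4` = 0.15)) {
  if (true_rbe_intercept < 1 || true_rbe_slope < 0)
    stop("config parameter 'true_rbe_intercept' must be >= 1 with non-negative 'true_rbe_slope' (RBE(l) >= 1 for l >= 0)",
         call. = FALSE)
  if (reference_threshold <= 0)
    stop("config parameter 'reference_threshold' must be positive", call. = FALSE)
  if (!is.null(target_incidence)) .check_prob(target_incidence, "target_incidence")
  if (length(grade_probs) != 3L || any(grade_probs < 0) ||
      abs(sum(grade_probs) - 1) > 1e-9)
    stop("config parameter 'grade_probs' must be a 3-vector over grades 2,3,4 summing to 1",
         call. = FALSE)
  names(grade_probs) <- c("2", "3", "4")
  structure(list(true_rbe_intercept = true_rbe_intercept,
                 true_rbe_slope = true_rbe_slope,
                 risk_intercept = risk_intercept,
                 risk_slope = risk_slope,
                 reference_threshold = reference_threshold,
                 target_incidence = target_incidence,
                 grade_probs = grade_probs),
            class = "outcome_config")
}

#' Bootstrap specification
#'
#' @param n_reps number of bootstrap resamples (default 1000).
#' @param seed RNG seed for resampling.
#' @param stratification `"modality_outcome"` (resample within modality x
#'   ORN strata, preserving group and event counts) or `"modality"`.
#' @param min_cases minimum ORN cases per modality a resample must retain;
#'   resamples below the floor are redrawn (only reachable under
#'   `"modality"` stratification).
#' @return an object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_reps = 1000L, seed = 1L,
                           stratification = c("modality_outcome", "modality"),
                           min_cases = 2L) {
  stratification <- match.arg(stratification)
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  if (min_cases < 1) stop("'min_cases' must be >= 1", call. = FALSE)
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 stratification = stratification,
                 min_cases = as.integer(min_cases)),
            class = "bootstrap_spec")
}
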