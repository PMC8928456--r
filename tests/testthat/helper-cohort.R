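# Shared fixtures: small synthetic cohorts built in code, cached per
# session so multiple tests can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

# Small, fast cohort: fewer voxels and a higher event rate than the
# shipped defaults so outcome-dependent stages stay well-defined at
# modest n.  Not a claim about the emulated cohort; defaults are tested
# separately.
small_cohort <- function(n = 400, seed = 42, target_incidence = 0.1,
                         n_voxels = 120) {
  key <- paste(n, seed, target_incidence, n_voxels, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  co <- generate_cohort(
    n,
    dose_cfg = dose_field_config(n_voxels = n_voxels),
    outcome_cfg = outcome_config(target_incidence = target_incidence),
    seed = seed)
  .fixture_cache[[key]] <- co
  co
}

default_cohort <- function(seed = 101, n = 1266) {
  key <- paste("default", seed, n, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  co <- generate_cohort(n, seed = seed)
  .fixture_cache[[key]] <- co
  co
}

# One patient's voxel set as a plain data.frame.
voxel_df <- function(volume, dose, let = rep(0, length(dose))) {
  data.frame(volume_cc = volume, dose_gy_rbe = dose, let_kev_um = let)
}

# Matched-cohort index table for a cohort (the common pipeline prefix).
matched_index_table <- function(cohort) {
  idx <- dvh_index_table(cohort)
  fit <- fit_propensity(cohort$records)
  m <- greedy_match(fit, cohort$records)
  idx[idx$patient_id %in% c(m$pairs$proton_id, m$pairs$photon_id), ]
}
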