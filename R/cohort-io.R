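# Plain-text cohort persistence: cohort.csv (one patient per row, booleans
# as 0/1, stage as I/II/III/IV/X), one voxel CSV per patient, and a
# manifest mapping patient_id -> sample file.

.bool_cols <- c("chemo", "hypertension", "diabetes", "dental_extraction",
                "smoking_history", "current_smoker",
                "oropharynx_or_oral_cavity", "orn")

.record_cols <- c("patient_id", "modality", "age", "gender", "stage",
                  "prescription_dose", .bool_cols[1:7], "orn", "orn_grade")

#' Write a cohort to a directory of delimited text files
#'
#' @param cohort an `orn_cohort`, or a list with `records` and `samples`.
#' @param directory_path output directory (created if missing).
#' @return invisibly, the manifest `data.frame` (`patient_id`, `file`).
#' @export
write_cohort <- function(cohort, directory_path) {
  records <- cohort$records
  samples <- data.table::as.data.table(cohort$samples)
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(directory_path, "samples"), showWarnings = FALSE)

  out <- records
  for (cl in .bool_cols) out[[cl]] <- as.integer(out[[cl]])
  write.csv(out, file.path(directory_path, "cohort.csv"),
            row.names = FALSE, quote = FALSE, na = "")

  manifest <- data.frame(patient_id = records$patient_id,
                         file = file.path("samples",
                                          paste0(records$patient_id, ".csv")),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    s <- samples[samples$patient_id == manifest$patient_id[i],
                 c("volume_cc", "dose_gy_rbe", "let_kev_um")]
    data.table::fwrite(s, file.path(directory_path, manifest$file[i]))
  }
  write.csv(manifest, file.path(directory_path, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

.io_stop <- function(file, msg, line = NA, column = NA) {
  loc <- sprintf("file '%s'", file)
  if (!is.na(line)) loc <- paste0(loc, sprintf(", line %d", line))
  if (!is.na(column)) loc <- paste0(loc, sprintf(", column '%s'", column))
  stop(paste0(loc, ": ", msg), call. = FALSE)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates column presence, value domains (non-negative volumes and
#' doses, zero LET for photon patients) and referential integrity between
#' the cohort table and the sample manifest.  Errors name the offending
#' file, line and column.
#'
#' @param directory_path directory containing `cohort.csv`,
#'   `manifest.csv` and `samples/`.
#' @return an object of class `orn_cohort` (configs absent).
#' @export
read_cohort <- function(directory_path) {
  cfile <- file.path(directory_path, "cohort.csv")
  mfile <- file.path(directory_path, "manifest.csv")
  if (!file.exists(cfile)) .io_stop(cfile, "not found")
  if (!file.exists(mfile)) .io_stop(mfile, "not found")
  records <- read.csv(cfile, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.record_cols, names(records))
  if (length(missing_cols))
    .io_stop(cfile, "missing required columns",
             column = paste(missing_cols, collapse = ", "))
  for (cl in .bool_cols) records[[cl]] <- records[[cl]] == 1
  records$orn_grade <- suppressWarnings(as.integer(records$orn_grade))
  bad <- which(records$orn & is.na(records$orn_grade))
  if (length(bad))
    .io_stop(cfile, "orn_grade must be present for ORN cases",
             line = bad[1] + 1L, column = "orn_grade")
  bad <- which(!records$orn & !is.na(records$orn_grade))
  if (length(bad))
    .io_stop(cfile, "orn_grade must be absent for non-ORN patients",
             line = bad[1] + 1L, column = "orn_grade")
  bad <- which(records$prescription_dose < 60)
  if (length(bad))
    .io_stop(cfile, "prescription_dose below 60 Gy[RBE]",
             line = bad[1] + 1L, column = "prescription_dose")
  if (!all(records$modality %in% c("photon", "proton")))
    .io_stop(cfile, "modality must be 'photon' or 'proton'",
             column = "modality")

  manifest <- read.csv(mfile, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "file") %in% names(manifest)))
    .io_stop(mfile, "missing required columns", column = "patient_id, file")
  orphan <- setdiff(records$patient_id, manifest$patient_id)
  if (length(orphan))
    .io_stop(mfile, sprintf("no sample file listed for patient '%s'", orphan[1]))

  sample_list <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sfile <- file.path(directory_path, manifest$file[i])
    if (!file.exists(sfile))
      .io_stop(sfile, sprintf("sample file for patient '%s' not found",
                              manifest$patient_id[i]))
    s <- data.table::fread(sfile)
    need <- c("volume_cc", "dose_gy_rbe", "let_kev_um")
    miss <- setdiff(need, names(s))
    if (length(miss))
      .io_stop(sfile, "missing required columns",
               column = paste(miss, collapse = ", "))
    bad <- which(s$volume_cc <= 0)
    if (length(bad))
      .io_stop(sfile, "voxel volume must be positive",
               line = bad[1] + 1L, column = "volume_cc")
    bad <- which(s$dose_gy_rbe < 0)
    if (length(bad))
      .io_stop(sfile, "dose must be non-negative",
               line = bad[1] + 1L, column = "dose_gy_rbe")
    bad <- which(s$let_kev_um < 0)
    if (length(bad))
      .io_stop(sfile, "LET must be non-negative",
               line = bad[1] + 1L, column = "let_kev_um")
    s$patient_id <- manifest$patient_id[i]
    sample_list[[i]] <- s
  }
  samples <- data.table::rbindlist(sample_list)
  data.table::setcolorder(samples, c("patient_id", "volume_cc",
                                     "dose_gy_rbe", "let_kev_um"))
  # photon patients must carry identically-zero LET
  pid_photon <- records$patient_id[records$modality == "photon"]
  bad_let <- samples[samples$patient_id %in% pid_photon &
                       samples$let_kev_um != 0, ]
  if (nrow(bad_let))
    .io_stop(file.path(directory_path, "samples"),
             sprintf("photon patient '%s' has non-zero LET",
                     bad_let$patient_id[1]))
  structure(list(records = records, samples = samples),
            class = "orn_cohort")
}
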