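# Dosimetry: cumulative DVH curves, DVH indices (VxGy, D0.01cc, Dmean)
# and dose-LET volume histograms (DLVH) computed directly from voxel
# samples.  Indices are exact sums over voxels; binned curves are for
# display only.

.check_samples <- function(samples) {
  if (is.null(samples$volume_cc) || is.null(samples$dose_gy_rbe))
    stop("samples must have columns 'volume_cc' and 'dose_gy_rbe'",
         call. = FALSE)
  if (nrow(samples) == 0L) stop("empty voxel set", call. = FALSE)
  if (any(samples$volume_cc <= 0)) stop("voxel volumes must be positive",
                                        call. = FALSE)
  if (any(samples$dose_gy_rbe < 0)) stop("doses must be non-negative",
                                         call. = FALSE)
  invisible(samples)
}

#' Cumulative dose-volume histogram
#'
#' Absolute volume (cc) with dose >= each grid value, on a regular dose
#' grid from 0 to just above the maximum voxel dose.
#'
#' @param samples one patient's voxels (`volume_cc`, `dose_gy_rbe`).
#' @param dose_resolution grid spacing, Gy (> 0); default 1.
#' @return class `dvh_curve`: list with `dose_grid`, `cumulative_volume`
#'   (cc), `total_volume`.
#' @export
compute_dvh <- function(samples, dose_resolution = 1) {
  .check_samples(samples)
  if (dose_resolution <= 0) stop("'dose_resolution' must be positive",
                                 call. = FALSE)
  dmax <- max(samples$dose_gy_rbe)
  grid <- seq(0, dmax + dose_resolution, by = dose_resolution)
  ord <- order(samples$dose_gy_rbe)
  dose_sorted <- samples$dose_gy_rbe[ord]
  # volume strictly below each sorted dose; cumulative_volume = total - below
  vol_cum <- cumsum(samples$volume_cc[ord])
  total <- vol_cum[length(vol_cum)]
  idx <- findInterval(grid, dose_sorted, left.open = TRUE)  # doses < g
  below <- c(0, vol_cum)[idx + 1L]
  structure(list(dose_grid = grid, cumulative_volume = total - below,
                 total_volume = total),
            class = "dvh_curve")
}

#' DVH indices: V40-V75 (cc), D0.01cc and Dmean (Gy[RBE])
#'
#' VxGy is the exact sum of voxel volumes with dose >= x.  Dmean is the
#' volume-weighted mean dose.  D0.01cc is resolved at voxel granularity:
#' voxels are sorted by descending dose and the dose of the voxel in which
#' cumulative volume first reaches 0.01 cc is reported (no sub-voxel
#' interpolation).  If total volume < 0.01 cc, `d001cc` is `NA` with a
#' warning.
#'
#' @param samples one patient's voxels (`volume_cc`, `dose_gy_rbe`).
#' @param v_levels dose levels (Gy[RBE]) for the volume indices.
#' @return class `dvh_indices`: named list `v40`, `v50`, `v60`, `v70`,
#'   `v75` (or `v<level>` for custom levels), `d001cc`, `dmean`,
#'   `total_volume`.
#' @export
dvh_indices <- function(samples, v_levels = c(40, 50, 60, 70, 75)) {
  .check_samples(samples)
  vol <- samples$volume_cc
  dose <- samples$dose_gy_rbe
  total <- sum(vol)
  vx <- vapply(v_levels, function(x) sum(vol[dose >= x]), numeric(1))
  names(vx) <- paste0("v", v_levels)
  ord <- order(dose, decreasing = TRUE)
  cumvol <- cumsum(vol[ord])
  if (total < 0.01) {
    warning("total volume < 0.01 cc: d001cc undefined", call. = FALSE)
    d001cc <- NA_real_
  } else {
    d001cc <- dose[ord][which(cumvol >= 0.01)[1]]
  }
  out <- c(as.list(vx),
           list(d001cc = d001cc, dmean = sum(vol * dose) / total,
                total_volume = total))
  class(out) <- "dvh_indices"
  out
}

#' Per-patient DVH index table for a cohort
#'
#' Computes all DVH indices for every patient, joined to modality and ORN
#' outcome.  Vectorized over the cohort's long sample table.
#'
#' @param cohort an `orn_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param v_levels dose levels for the volume indices.
#' @return a `data.frame`: `patient_id`, `modality`, `orn`, `v40` ...
#'   `v75`, `d001cc`, `dmean`.
#' @export
dvh_index_table <- function(cohort, v_levels = c(40, 50, 60, 70, 75)) {
  s <- data.table::as.data.table(cohort$samples)
  idx <- s[, {
    total <- sum(volume_cc)
    vx <- lapply(v_levels, function(x) sum(volume_cc[dose_gy_rbe >= x]))
    names(vx) <- paste0("v", v_levels)
    ord <- order(dose_gy_rbe, decreasing = TRUE)
    d001 <- if (total < 0.01) NA_real_ else
      dose_gy_rbe[ord][which(cumsum(volume_cc[ord]) >= 0.01)[1]]
    c(vx, list(d001cc = d001, dmean = sum(volume_cc * dose_gy_rbe) / total))
  }, by = patient_id]
  rec <- cohort$records[, c("patient_id", "modality", "orn")]
  out <- merge(rec, as.data.frame(idx), by = "patient_id", sort = TRUE)
  out
}

#' Dose-LET volume histogram surface
#'
#' Fraction of structure volume with dose >= d AND LET >= l on an explicit
#' rectangular grid.  For photon patients (all-zero LET) the surface
#' collapses to the DVH at l = 0 and vanishes for l > 0.
#'
#' @param samples one patient's voxels (`volume_cc`, `dose_gy_rbe`,
#'   `let_kev_um`).
#' @param dose_grid ascending dose grid, Gy[RBE]; default 1-Gy spacing
#'   from 0 to the maximum voxel dose.
#' @param let_grid ascending LET grid, keV/um; default 0.25 keV/um spacing.
#' @return class `dlvh_surface`: list with `dose_grid`, `let_grid`,
#'   `volume_fraction` (matrix `[dose, let]`), `total_volume`.
#' @export
compute_dlvh <- function(samples, dose_grid = NULL, let_grid = NULL) {
  .check_samples(samples)
  if (is.null(samples$let_kev_um))
    stop("samples must have column 'let_kev_um'", call. = FALSE)
  if (any(samples$let_kev_um < 0)) stop("LET must be non-negative",
                                        call. = FALSE)
  if (is.null(dose_grid))
    dose_grid <- seq(0, max(samples$dose_gy_rbe) + 1, by = 1)
  if (is.null(let_grid))
    let_grid <- seq(0, max(samples$let_kev_um) + 0.25, by = 0.25)
  if (is.unsorted(dose_grid, strictly = TRUE) ||
      is.unsorted(let_grid, strictly = TRUE))
    stop("grids must be strictly ascending", call. = FALSE)
  total <- sum(samples$volume_cc)
  vf <- vapply(let_grid, function(l) {
    keep <- samples$let_kev_um >= l
    vol <- samples$volume_cc[keep]
    dose <- samples$dose_gy_rbe[keep]
    vapply(dose_grid, function(d) sum(vol[dose >= d]), numeric(1))
  }, numeric(length(dose_grid))) / total
  vf <- matrix(vf, nrow = length(dose_grid), ncol = length(let_grid))
  structure(list(dose_grid = dose_grid, let_grid = let_grid,
                 volume_fraction = vf, total_volume = total),
            class = "dlvh_surface")
}

#' Iso-volume contour (DLx%) of a DLVH surface
#'
#' For each dose-grid value whose column reaches the requested volume
#' fraction, returns the largest LET at which the fraction is still >=
#' `percent`/100.  Where the level crossing falls between LET grid points
#' with support on both sides, the crossing is located by linear
#' interpolation; where the surface drops to zero beyond the last
#' supported grid point, the top of support at grid resolution is
#' returned (step surfaces are not smoothed past their support).
#'
#' @param surface a `dlvh_surface`.
#' @param percent volume percentage in (0, 100); conventionally 5, 20, 50.
#' @return class `dlvh_contour`: `data.frame` with `dose` and `let`
#'   (rows only where the contour is defined), plus attribute `percent`.
#' @export
dlvh_contour <- function(surface, percent) {
  stopifnot(inherits(surface, "dlvh_surface"))
  if (!is.numeric(percent) || length(percent) != 1L ||
      percent <= 0 || percent >= 100)
    stop("'percent' must lie strictly between 0 and 100", call. = FALSE)
  p <- percent / 100
  vf <- surface$volume_fraction
  lg <- surface$let_grid
  nl <- length(lg)
  rows <- lapply(seq_along(surface$dose_grid), function(i) {
    col <- vf[i, ]
    if (col[1] < p) return(NULL)
    j <- max(which(col >= p))
    l <- if (j == nl || col[j] <= p || col[j + 1L] <= 0) {
      lg[j]
    } else {
      lg[j] + (lg[j + 1L] - lg[j]) * (col[j] - p) / (col[j] - col[j + 1L])
    }
    data.frame(dose = surface$dose_grid[i], let = l)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(dose = numeric(0), let = numeric(0))
  attr(out, "percent") <- percent
  class(out) <- c("dlvh_contour", "data.frame")
  out
}
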