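test_that("DVH curve matches hand counts and step functions", {
  s <- voxel_df(rep(0.5, 4), c(10, 20, 30, 40))
  curve <- compute_dvh(s, dose_resolution = 5)
  expect_equal(curve$cumulative_volume[curve$dose_grid == 15], 1.5)
  expect_equal(curve$cumulative_volume[curve$dose_grid == 0], 2.0)
  expect_true(all(diff(curve$cumulative_volume) <= 0))

  u <- compute_dvh(voxel_df(rep(1, 60), rep(50, 60)), dose_resolution = 1)
  expect_true(all(u$cumulative_volume[u$dose_grid <= 50] == 60))
  expect_true(all(u$cumulative_volume[u$dose_grid > 50] == 0))

  expect_error(compute_dvh(voxel_df(numeric(0), numeric(0))), "empty")
  expect_error(compute_dvh(s, dose_resolution = 0), "positive")
})

test_that("DVH curve equals a brute-force recount on random voxel sets", {
  set.seed(11)
  s <- voxel_df(runif(200, 0.05, 0.3), runif(200, 0, 75))
  curve <- compute_dvh(s, dose_resolution = 2.5)
  brute <- vapply(curve$dose_grid, function(g)
    sum(s$volume_cc[s$dose_gy_rbe >= g]), numeric(1))
  expect_equal(curve$cumulative_volume, brute, tolerance = 1e-12)
})

test_that("DVH indices match hand computation and the voxel-granular D0.01cc", {
  s <- voxel_df(rep(0.5, 4), c(10, 20, 30, 40))
  ix <- dvh_indices(s, v_levels = c(15, 40, 50))
  expect_equal(ix$dmean, 25)
  expect_equal(ix$v15, 1.5)
  expect_equal(ix$v40, 0.5)
  expect_equal(ix$v50, 0)

  # two hottest 0.005-cc voxels span 0.01 cc -> d001cc = second dose
  s2 <- voxel_df(rep(0.005, 5), c(70, 68, 66, 64, 62))
  expect_equal(dvh_indices(s2)$d001cc, 68)

  # total volume below 0.01 cc -> flagged undefined
  expect_warning(ix3 <- dvh_indices(voxel_df(0.005, 50)), "d001cc")
  expect_true(is.na(ix3$d001cc))
})

test_that("DVH indices match a brute-force sort-and-accumulate oracle", {
  set.seed(12)
  s <- voxel_df(runif(500, 0.01, 0.2), runif(500, 0, 80))
  ix <- dvh_indices(s)
  for (L in c(40, 50, 60, 70, 75))
    expect_equal(ix[[paste0("v", L)]],
                 sum(s$volume_cc[s$dose_gy_rbe >= L]))
  expect_equal(ix$dmean, weighted.mean(s$dose_gy_rbe, s$volume_cc))
  ord <- order(s$dose_gy_rbe, decreasing = TRUE)
  expect_equal(ix$d001cc,
               s$dose_gy_rbe[ord][which(cumsum(s$volume_cc[ord]) >= 0.01)[1]])
  # monotone chain
  expect_true(ix$v40 >= ix$v50 && ix$v50 >= ix$v60 &&
                ix$v60 >= ix$v70 && ix$v70 >= ix$v75)
})

test_that("indices are invariant to voxel reordering and half-splitting", {
  set.seed(13)
  s <- voxel_df(runif(80, 0.05, 0.4), runif(80, 10, 70))
  base <- dvh_indices(s)
  perm <- s[sample.int(nrow(s)), ]
  expect_equal(dvh_indices(perm), base)
  split <- voxel_df(rep(s$volume_cc / 2, 2), rep(s$dose_gy_rbe, 2))
  expect_equal(dvh_indices(split), base, tolerance = 1e-12)
})

test_that("index table agrees with per-patient indices and carries outcome", {
  co <- small_cohort()
  tab <- dvh_index_table(co)
  expect_equal(nrow(tab), nrow(co$records))
  id <- co$records$patient_id[17]
  one <- dvh_indices(patient_samples(co, id))
  row <- tab[tab$patient_id == id, ]
  for (ix in c("v40", "v50", "v60", "v70", "v75", "d001cc", "dmean"))
    expect_equal(row[[ix]], one[[ix]], tolerance = 1e-12)
  expect_true(all(tab$v40 >= tab$v50 & tab$v50 >= tab$v60 &
                    tab$v60 >= tab$v70 & tab$v70 >= tab$v75))
})

test_that("DLVH surface matches hand enumeration and brute force", {
  s <- voxel_df(c(1, 1), c(50, 30), c(3, 6))
  surf <- compute_dlvh(s, dose_grid = c(0, 40), let_grid = c(0, 2, 4))
  expect_equal(surf$volume_fraction[1, 1], 1)   # (0, 0)
  expect_equal(surf$volume_fraction[2, 2], 0.5) # (40, 2)
  expect_true(all(surf$volume_fraction >= 0 & surf$volume_fraction <= 1))

  set.seed(14)
  r <- voxel_df(runif(200, 0.05, 0.3), runif(200, 0, 70), runif(200, 0, 9))
  dg <- seq(0, 70, by = 5); lg <- seq(0, 9, by = 0.75)
  surf2 <- compute_dlvh(r, dg, lg)
  brute <- outer(seq_along(dg), seq_along(lg), Vectorize(function(i, j)
    sum(r$volume_cc[r$dose_gy_rbe >= dg[i] & r$let_kev_um >= lg[j]])))
  expect_equal(surf2$volume_fraction, brute / sum(r$volume_cc),
               tolerance = 1e-12)
  # non-increasing along both axes
  expect_true(all(apply(surf2$volume_fraction, 2, diff) <= 0))
  expect_true(all(apply(surf2$volume_fraction, 1, diff) <= 0))
})

test_that("DVH is the LET=0 marginal of the DLVH surface", {
  co <- small_cohort()
  pid <- co$records$patient_id[co$records$modality == "proton"][1]
  s <- patient_samples(co, pid)
  dg <- seq(0, 80, by = 4)
  surf <- compute_dlvh(s, dg, c(0, 2, 4))
  curve_vol <- vapply(dg, function(g)
    sum(s$volume_cc[s$dose_gy_rbe >= g]), numeric(1))
  expect_equal(surf$volume_fraction[, 1] * surf$total_volume, curve_vol,
               tolerance = 1e-9)
})

test_that("photon DLVH collapses to the DVH at l = 0", {
  s <- voxel_df(rep(1, 3), c(10, 20, 30))
  surf <- compute_dlvh(s, c(0, 15, 25), c(0, 1))
  expect_equal(surf$volume_fraction[, 1], c(1, 2 / 3, 1 / 3))
  expect_equal(surf$volume_fraction[, 2], c(0, 0, 0))
})

test_that("DLVH contours follow the spec examples and stay monotone", {
  # uniform structure: DL50% sits at the top of LET support
  u <- voxel_df(rep(1, 10), rep(50, 10), rep(4, 10))
  surf <- compute_dlvh(u, dose_grid = c(0, 40), let_grid = c(0, 2, 4, 6))
  cont <- dlvh_contour(surf, 50)
  expect_equal(cont$let[cont$dose == 40], 4)

  # two-voxel example: at dose 40 only the (50, 3) voxel remains
  s <- voxel_df(c(1, 1), c(50, 30), c(3, 6))
  surf2 <- compute_dlvh(s, dose_grid = c(0, 40), let_grid = c(0, 3, 6))
  cont2 <- dlvh_contour(surf2, 50)
  expect_equal(cont2$let[cont2$dose == 40], 3)

  expect_error(dlvh_contour(surf, 0), "percent")
  expect_error(dlvh_contour(surf, 100), "percent")

  # contour LET non-increasing in dose on a realistic surface
  co <- small_cohort()
  pid <- co$records$patient_id[co$records$modality == "proton"][2]
  surf3 <- compute_dlvh(patient_samples(co, pid))
  for (p in c(5, 20, 50)) {
    cont3 <- dlvh_contour(surf3, p)
    if (nrow(cont3) > 1) expect_true(all(diff(cont3$let) <= 1e-9))
  }
})
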