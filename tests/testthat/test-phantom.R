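# Digital phantom generator: shell construction, artifact zones, defects,
# Poisson noise and the composed study builder.

test_that("noiseless shell has translational symmetry and exact total counts", {
  geom <- lv_geometry(outer_radius_mm = 30, wall_thickness_mm = 10,
                      count_density = 100)
  czt <- build_ac_volume(geom, camera_profile("czt"))
  sums <- apply(czt, 3, sum)
  shell_z <- which(sums > 0)
  for (z in shell_z) {
    expect_identical(czt[, , z], czt[, , shell_z[1]])
  }

  n_shell <- oracle_shell_voxels(dim(czt), attr(czt, "center"),
                                 attr(czt, "voxel_size_mm"), 30, 20, shell_z)
  expect_equal(sum(czt), 100 * n_shell, tolerance = 1e-10)
  expect_equal(sum(czt > 0), n_shell)

  # coarser conventional grid: annulus present on every shell slice, but
  # fewer voxels per slice than at 4 mm
  ven <- build_ac_volume(geom, camera_profile("ventri"))
  ven_z <- which(apply(ven, 3, sum) > 0)
  expect_gt(length(ven_z), 0)
  expect_lt(sum(ven[, , ven_z[1]] > 0), sum(czt[, , shell_z[1]] > 0))
})

test_that("geometry that cannot fit the analyzed slices is rejected", {
  short <- lv_geometry(axial_length_mm = 20)
  expect_error(build_ac_volume(short, camera_profile("czt")), "too short")
})

test_that("artifact zones scale exactly the targeted voxels and sector sums", {
  ac <- build_ac_volume(lv_geometry(), camera_profile("czt"))

  # empty zone list: identity
  empty <- artifact_spec(tibble::tibble(
    angle_start_deg = numeric(), angle_end_deg = numeric(),
    slice_start = integer(), slice_end = integer(), transmission = numeric()))
  expect_identical(apply_artifact(ac, empty), ac)

  # full-circle, all-slice zone: uniform halving of every myocardial voxel
  n_shell_slices <- sum(apply(ac, 3, sum) > 0)
  whole <- artifact_spec(tibble::tibble(
    angle_start_deg = 0, angle_end_deg = 360,
    slice_start = 1L, slice_end = n_shell_slices, transmission = 0.5))
  halved <- apply_artifact(ac, whole)
  expect_equal(halved, ac * 0.5, tolerance = 1e-12, ignore_attr = TRUE)

  # the AC input is never modified
  before <- ac + 0
  invisible(apply_artifact(ac, whole))
  expect_identical(ac, before)

  # sector-aligned zones: brute-force sector sums show exactly f * AC in the
  # 68 targeted segments and identity elsewhere
  zones <- sector_artifact(c(105, 135, 165, 195), 1, 17,
                           c(0.70, 0.70, 0.76, 0.76))
  nac <- apply_artifact(ac, zones)
  slices <- select_slices(ac, camera_profile("czt"))
  centers <- slice_centers(ac, slices)
  s_ac <- oracle_sector_sums(ac, slices, centers)
  s_nac <- oracle_sector_sums(nac, slices, centers, reference = ac)
  f_expect <- matrix(1, 20, 12)
  f_expect[1:17, 4:5] <- 0.70   # sectors centred 105 and 135 degrees
  f_expect[1:17, 6:7] <- 0.76   # sectors centred 165 and 195 degrees
  expect_equal(s_nac / s_ac, f_expect, tolerance = 1e-12)
})

test_that("invalid artifact zones are rejected", {
  expect_error(sector_artifact(c(105, 135), 1, 17, 1.0), "strictly in")
  expect_error(sector_artifact(c(105, 135), 1, 17, 0), "strictly in")
  overlapping <- tibble::tibble(
    angle_start_deg = c(90, 100), angle_end_deg = c(120, 130),
    slice_start = c(1L, 5L), slice_end = c(10L, 8L),
    transmission = c(0.7, 0.8))
  expect_error(artifact_spec(overlapping), "overlap")
  # same angles but disjoint slice ranges are fine
  overlapping$slice_start <- c(1L, 11L)
  overlapping$slice_end <- c(10L, 12L)
  expect_s3_class(artifact_spec(overlapping), "artifact_spec")
})

test_that("defects realize the requested volume and hit both volumes", {
  geom <- lv_geometry()
  ac <- build_ac_volume(geom, camera_profile("czt"))
  vox_cm3 <- attr(ac, "voxel_size_mm")^3 / 1000

  res <- insert_defect(ac, ac, anterior_defect(), geom)
  expect_lte(abs(res$realized_volume_cm3 - 2.1), vox_cm3)
  expect_equal(sum(res$defect_mask), round(2.1 / vox_cm3))
  # uptake 0: chosen voxels zeroed identically in both volumes
  expect_true(all(res$ac[res$defect_mask] == 0))
  expect_identical(res$ac, res$nac)
  # defect sits in the anterior wall: mean angular position near 0 degrees
  idx <- which(res$defect_mask, arr.ind = TRUE)
  ctr <- attr(ac, "center")
  ang <- (atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2]) * 180 / pi) %% 360
  expect_lt(abs(ang_diff_deg(circ_mean_deg(ang), 0)), 15)

  # uptake 1 is the identity
  full <- insert_defect(ac, ac, defect_spec(0, 40, 2.1, uptake_factor = 1 - 1e-12),
                        geom)
  expect_equal(full$ac, ac, tolerance = 1e-9, ignore_attr = TRUE)

  # a defect larger than the shell warns and clips
  expect_warning(insert_defect(ac, ac, defect_spec(0, 40, 1e4), geom),
                 "clipped")
})

test_that("poisson noise is reproducible, preserves zeros, and is unbiased", {
  vol <- array(c(rep(0, 50), rep(50, 10000)), dim = c(50 + 10000, 1, 1))
  a <- add_poisson_noise(vol, seed = 99)
  b <- add_poisson_noise(vol, seed = 99)
  expect_identical(a, b)
  expect_true(all(a[1:50, , ] == 0))
  se <- sqrt(50 / 10000)
  expect_lt(abs(mean(a[-(1:50), , ]) - 50), 3 * se)
  expect_error(add_poisson_noise(array(-1, dim = c(1, 1, 1))), "non-negative")
})

test_that("generate_study composes reproducibly with full truth bookkeeping", {
  zones <- sector_artifact(c(165, 195), 1, 10, 0.7)
  s1 <- generate_study(camera_profile("czt"), artifact = zones,
                       defect = anterior_defect(), noise = TRUE, seed = 31)
  s2 <- generate_study(camera_profile("czt"), artifact = zones,
                       defect = anterior_defect(), noise = TRUE, seed = 31)
  expect_identical(s1$nac, s2$nac)
  expect_identical(s1$ac, s2$ac)

  # artifact and defect truth masks are disjoint when specified disjoint
  expect_equal(sum(s1$truth$artifact_voxel_mask & s1$truth$defect_mask), 0)
  expect_s3_class(s1$truth$segment_mask, "tbl_df")
  expect_equal(sum(s1$truth$segment_mask$attenuated), 2 * 10)

  # no artifact, no defect, no noise: NAC equals AC exactly
  null_study <- generate_study(camera_profile("ventri"))
  expect_identical(null_study$nac, null_study$ac)
})
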