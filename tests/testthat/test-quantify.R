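# Ratio map, threshold delineation and the extent / localization / depth
# metrics, including the defect-invisibility control.

make_grid <- function(raw, n_slices = 1) {
  grid <- tidyr::expand_grid(slice = seq_len(n_slices), sector = 1:12)
  grid$z_index <- grid$slice
  grid$sector_center_deg <- 30 * (grid$sector - 1) + 15
  grid$raw_counts <- raw
  grid$value <- raw / sum(raw)
  class(grid) <- c("sector_grid", class(grid))
  grid
}

test_that("ratio map: identity, renormalization algebra, undefined segments", {
  czt <- camera_profile("czt")
  clean <- generate_study(czt)
  grids <- sectorize_study(clean)
  r <- compute_ratio(grids$nac, grids$ac)
  expect_true(all(r$defined))
  expect_equal(r$ratio, rep(1, 240), tolerance = 1e-12)

  # depress one full sector column to 0.8: closed-form renormalization says
  # unaffected segments sit at T/(T - 0.2 c) and the column at 0.8 times that
  study <- generate_study(czt, artifact = sector_artifact(15, 1, 20, 0.8))
  r2 <- compute_ratio(sectorize_study(study)$nac, sectorize_study(study)$ac)
  carried <- 20 / 240                      # count share of the depressed column
  renorm <- 1 / (1 - 0.2 * carried)
  expect_equal(r2$ratio[r2$sector == 1], rep(0.8 * renorm, 20),
               tolerance = 1e-10)
  expect_equal(r2$ratio[r2$sector != 1], rep(renorm, 220), tolerance = 1e-10)

  # zero AC counts: undefined, never infinite, never artifact
  ac_raw <- c(0, rep(10, 11))
  nac_raw <- c(0, rep(10, 10), 5)
  r3 <- compute_ratio(make_grid(nac_raw), make_grid(ac_raw))
  expect_false(r3$defined[1])
  expect_true(is.na(r3$ratio[1]))
  mask3 <- delineate(r3, 0.9)
  expect_false(mask3$artifact[1])
  expect_true(mask3$artifact[12])

  # mismatched grids are rejected
  expect_error(compute_ratio(make_grid(rep(1, 24), 2), make_grid(rep(1, 12))),
               "share shape")
})

test_that("delineation is strictly below threshold and monotone", {
  r <- random_ratio_map(n_slices = 1, seed = 2)
  r$ratio[1:3] <- c(0.95, 0.89, 0.91)
  m90 <- delineate(r, 0.90)
  expect_identical(m90$artifact[1:3], c(FALSE, TRUE, FALSE))
  m85 <- delineate(r, 0.85)
  expect_identical(m85$artifact[1:3], c(FALSE, FALSE, FALSE))
  # boundary: a ratio exactly at the threshold is not artifact
  r$ratio[4] <- 0.90
  expect_false(delineate(r, 0.90)$artifact[4])
  expect_error(delineate(r, 1.2), "strictly in")

  # monotonicity over random maps: a higher threshold never shrinks the mask
  for (seed in 1:5) {
    rr <- random_ratio_map(n_slices = 5, seed = seed)
    th <- sort(stats::runif(2, 0.4, 0.999))
    lo <- delineate(rr, th[1])$artifact
    hi <- delineate(rr, th[2])$artifact
    expect_true(all(hi[lo]))
    expect_lte(artifact_extent(delineate(rr, th[1])),
               artifact_extent(delineate(rr, th[2])))
  }
})

test_that("extent is the artifact fraction of all analyzed segments", {
  r <- random_ratio_map(n_slices = 12, seed = 3)   # 144 segments
  m <- delineate(r, 0.9)
  m$artifact <- rep(FALSE, 144)
  expect_equal(artifact_extent(m), 0)
  m$artifact[sample.int(144, 36)] <- TRUE
  expect_equal(artifact_extent(m), 0.25)
  withr::with_seed(11, m$artifact <- stats::runif(144) < 0.3)
  expect_equal(artifact_extent(m), sum(m$artifact) / 144)
})

test_that("localization handles symmetry, wrap-around and degenerate masks", {
  r <- random_ratio_map(n_slices = 2, seed = 5)
  set_mask <- function(centers) {
    r$artifact <- r$sector_center_deg %in% centers
    r
  }
  expect_equal(artifact_localization(set_mask(c(105, 135, 165, 195))), 150)
  expect_equal(artifact_localization(set_mask(c(345, 15))), 0)
  expect_equal(artifact_localization(set_mask(165)), 165)
  expect_warning(loc <- artifact_localization(set_mask(numeric())), "empty")
  expect_true(is.na(loc))
  expect_warning(loc2 <- artifact_localization(set_mask(c(15, 195))),
                 "resultant")
  expect_true(is.na(loc2))

  # depression-weighted variant pulls towards the deeper segment
  r$artifact <- r$sector_center_deg %in% c(105, 165) & r$slice == 1
  r$ratio[r$artifact] <- c(0.5, 0.85)
  w <- artifact_localization(r, weighted = TRUE)
  expect_lt(ang_diff_deg(w, 135), 0)  # closer to the deep 105-degree segment
})

test_that("depth equals a sort-and-average oracle with deterministic ties", {
  for (seed in 1:4) {
    r <- random_ratio_map(n_slices = 6, seed = 10 + seed)
    withr::with_seed(seed, r$artifact <- stats::runif(nrow(r)) < 0.25)
    if (!any(r$artifact)) next
    expect_equal(artifact_depth(r),
                 oracle_depth(r$nac_value, r$slice, r$sector, r$artifact),
                 tolerance = 1e-12)
    expect_equal(artifact_depth(r, source = "ac"),
                 oracle_depth(r$ac_value, r$slice, r$sector, r$artifact),
                 tolerance = 1e-12)
  }

  # mask covering everything: mean(all)/mean(top 30%) <= 1, equality iff flat
  flat <- random_ratio_map(n_slices = 2, seed = 1)
  flat$nac_value <- rep(1 / 24, 24)
  flat$artifact <- TRUE
  expect_equal(artifact_depth(flat), 1, tolerance = 1e-12)
  rough <- random_ratio_map(n_slices = 2, seed = 2)
  rough$artifact <- TRUE
  expect_lt(artifact_depth(rough), 1)

  expect_error(artifact_depth(flat, top_fraction = 0.01), "no segments")
  flat$artifact <- FALSE
  expect_warning(d <- artifact_depth(flat), "empty")
  expect_true(is.na(d))
})

test_that("quantify_study: null pipeline, exact fixture recovery, truth mask", {
  czt <- camera_profile("czt")
  null_metrics <- quantify_study(generate_study(czt))
  expect_equal(null_metrics$extent_fraction, 0)
  expect_true(is.na(null_metrics$localization_deg))
  expect_true(is.na(null_metrics$depth_fraction))

  study <- reference_phantom("czt")
  m <- quantify_study(study)
  expect_equal(m$extent_fraction, 68 / 240, tolerance = 1e-12)
  expect_equal(m$localization_deg, 150, tolerance = 1e-9)
  expect_equal(m$depth_fraction, 0.73, tolerance = 1e-9)
  # the delineated mask equals the injected truth segment by segment
  truth <- study$truth$segment_mask
  joined <- dplyr::left_join(m$mask, truth, by = c("slice", "sector"))
  expect_identical(joined$artifact, joined$attenuated)

  # tidy/glance surface the same numbers
  td <- tidy(m)
  expect_equal(td$extent_pct, 28)
  expect_equal(td$depth_pct, 73)
  expect_equal(glance(m)$threshold_used, 0.90)
})

test_that("a true defect is invisible to the ratio-based metrics", {
  plain <- reference_phantom("czt")
  with_defect <- reference_phantom("czt", defect = anterior_defect())
  m0 <- quantify_study(plain)
  m1 <- quantify_study(with_defect)
  expect_identical(m1$n_artifact_segments, m0$n_artifact_segments)
  expect_identical(m1$mask$artifact, m0$mask$artifact)
  expect_equal(m1$extent_fraction, m0$extent_fraction)
  expect_equal(m1$localization_deg, m0$localization_deg, tolerance = 1e-9)
  expect_equal(m1$depth_fraction, m0$depth_fraction, tolerance = 1e-12)

  # ratios change only by a common renormalization constant where defined
  both <- m0$mask$defined & m1$mask$defined
  scale <- m1$mask$ratio[both] / m0$mask$ratio[both]
  expect_lt(diff(range(scale)), 1e-10)

  # a defect alone never creates an artifact
  defect_only <- generate_study(camera_profile("czt"),
                                defect = anterior_defect())
  expect_equal(quantify_study(defect_only)$extent_fraction, 0)
})

test_that("optional connectivity filtering keeps the largest component", {
  czt <- camera_profile("czt")
  two_blobs <- artifact_spec(tibble::tibble(
    angle_start_deg = c(120, 300), angle_end_deg = c(210, 330),
    slice_start = c(1L, 1L), slice_end = c(17L, 2L),
    transmission = c(0.7, 0.7)))
  study <- generate_study(czt, artifact = two_blobs)
  loose <- quantify_study(study)
  tight <- quantify_study(study, connectivity = TRUE)
  expect_equal(loose$n_artifact_segments, 3 * 17 + 2)
  expect_equal(tight$n_artifact_segments, 3 * 17)
})
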