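# Independent brute-force oracles, written as plain scalar loops so they share
# no code path with the vectorized implementation.

# Per-segment sums by looping over every voxel of every analyzed slice and
# binning its centre angle into 30-degree sectors. Membership: positive counts
# in `reference` (defaults to the volume itself).
oracle_sector_sums <- function(volume, slices, centers, reference = NULL) {
  reference <- if (is.null(reference)) volume else reference
  d <- dim(volume)
  sums <- matrix(0, length(slices), 12)
  for (i in seq_along(slices)) {
    z <- slices[i]
    for (x in seq_len(d[1])) {
      for (y in seq_len(d[2])) {
        if (reference[x, y, z] <= 0) next
        ang <- atan2(x - centers[i, 1], y - centers[i, 2]) * 180 / pi
        if (ang < 0) ang <- ang + 360
        k <- floor(ang / 30) + 1
        if (k > 12) k <- 12
        sums[i, k] <- sums[i, k] + volume[x, y, z]
      }
    }
  }
  sums
}

# Depth by explicit sort: mean over artifact segments / mean over the k
# highest-count segments, ties broken by (slice, sector) ascending.
oracle_depth <- function(values, slice, sector, artifact, top_fraction = 0.30) {
  k <- round(top_fraction * length(values))
  df <- data.frame(values, slice, sector)
  df <- df[order(-df$values, df$slice, df$sector), ]
  mean(values[artifact]) / mean(df$values[seq_len(k)])
}

# Shell voxel count by looping over the grid and testing the annulus radii.
oracle_shell_voxels <- function(d, center, voxel_mm, r_out, r_in, z_shell) {
  n <- 0L
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      r <- sqrt((x - center[1])^2 + (y - center[2])^2) * voxel_mm
      if (r <= r_out && r > r_in) n <- n + 1L
    }
  }
  n * length(z_shell)
}

# Small random ratio map for property tests.
random_ratio_map <- function(n_slices = 4, seed = 1) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(slice = seq_len(n_slices), sector = 1:12)
    grid$sector_center_deg <- 30 * (grid$sector - 1) + 15
    grid$nac_value <- stats::runif(nrow(grid), 0.5, 1.5)
    grid$ac_value <- stats::runif(nrow(grid), 0.5, 1.5)
    grid$defined <- TRUE
    grid$ratio <- grid$nac_value / grid$ac_value
    class(grid) <- c("ratio_map", class(grid))
    grid
  })
}
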