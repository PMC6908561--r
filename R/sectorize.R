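# Short-axis sectorization: slice selection from the base, per-slice
# count-weighted centres, and binning of myocardial voxels into 12 half-open
# 30-degree sectors, normalized to the grand total over all analyzed segments.

# In-plane polar coordinates of every voxel centre: theta in the convention
# frame (0 = anterior = +y image axis, increasing towards +x = lateral),
# radius in mm. Returns matrices of dim (nx, ny).
polar_grid <- function(nx, ny, center, voxel_size_mm,
                       convention = angular_convention()) {
  dx <- matrix(seq_len(nx) - center[1], nx, ny)
  dy <- matrix(seq_len(ny) - center[2], nx, ny, byrow = TRUE)
  theta <- (atan2(dx, dy) * 180 / pi - convention$rotation_deg) %% 360
  list(theta_deg = theta, r_mm = sqrt(dx^2 + dy^2) * voxel_size_mm)
}

#' Select the analyzed short-axis slices
#'
#' Returns exactly `profile$n_slices` slice indices, starting at the most
#' basal slice whose count sum exceeds a detection floor and proceeding
#' apically through the non-empty slices. The floor is a fraction of the
#' maximum slice count sum, which makes the selection robust to noise-only
#' slices.
#'
#' @param volume 3-D count array, z running base -> apex.
#' @param profile A [camera_profile()]; `n_slices` slices are selected.
#' @param floor_frac Detection floor as a fraction of the maximum slice sum.
#' @return Integer vector of `n_slices` z indices.
#' @export
select_slices <- function(volume, profile, floor_frac = 0.01) {
  sums <- apply(volume, 3, sum)
  if (max(sums) <= 0) abort("volume has no counts")
  nonempty <- which(sums > floor_frac * max(sums))
  if (length(nonempty) < profile$n_slices) {
    abort(sprintf("only %d non-empty slices; profile needs %d",
                  length(nonempty), profile$n_slices))
  }
  nonempty[seq_len(profile$n_slices)]
}

#' Count-weighted in-plane centres of slices
#'
#' The centroid of each slice's counts, used as the origin of the angular
#' sectorization. Computed on the AC image and reused for the paired NAC
#' slices, so both grids of a study share identical geometry.
#'
#' @param volume 3-D count array.
#' @param slices z indices of the slices.
#' @return A `length(slices) x 2` matrix of (x, y) voxel coordinates.
#' @export
slice_centers <- function(volume, slices) {
  t(vapply(slices, function(z) {
    s <- volume[, , z]
    tot <- sum(s)
    if (tot <= 0) abort(sprintf("slice %d has no counts", z))
    c(sum(row(s) * s), sum(col(s) * s)) / tot
  }, numeric(2)))
}

#' Sectorize a short-axis volume into the slice x 12-sector grid
#'
#' Assigns each myocardial voxel of each analyzed slice to exactly one of 12
#' equal 30-degree sectors by the angle of its centre about the slice centre
#' (half-open bins, no splitting), sums raw counts per (slice, sector) segment,
#' and normalizes by the grand total over all analyzed segments.
#'
#' @param volume 3-D count array.
#' @param slices Analyzed z indices, most basal first (see [select_slices()]).
#' @param centers Per-slice in-plane centres (see [slice_centers()]); defaults
#'   to the centroids of `membership`'s reference volume.
#' @param convention [angular_convention()].
#' @param membership Myocardium membership reference: `NULL` to use voxels
#'   with positive counts in `volume` itself, a numeric volume (e.g. the paired
#'   AC image) whose positive voxels define membership, or a logical array.
#' @param r_min_mm,r_max_mm Optional radial band (mm, about the slice centre)
#'   restricting membership.
#' @param voxel_size_mm Voxel size; taken from the volume's attribute when
#'   absent (needed only for a finite radial band).
#' @return A `sector_grid` tibble with columns `slice` (1 = most basal
#'   analyzed), `z_index`, `sector`, `sector_center_deg`, `raw_counts`,
#'   `value` (normalized counts summing to 1), and attributes `total_counts`
#'   and `convention`.
#' @export
sectorize <- function(volume, slices, centers = NULL,
                      convention = angular_convention(), membership = NULL,
                      r_min_mm = 0, r_max_mm = Inf, voxel_size_mm = NULL) {
  d <- dim(volume)
  vox <- voxel_size_mm %||% attr(volume, "voxel_size_mm") %||% 1
  ref <- membership %||% volume
  mem_slice <- function(z) {
    if (is.logical(ref)) ref[, , z] else ref[, , z] > 0
  }
  if (is.null(centers)) {
    centers <- slice_centers(if (is.logical(ref)) volume else ref, slices)
  }
  stopifnot(nrow(centers) == length(slices))

  n_sec <- convention$n_sectors
  raw <- matrix(0, length(slices), n_sec)
  for (i in seq_along(slices)) {
    z <- slices[i]
    pol <- polar_grid(d[1], d[2], centers[i, ], vox, convention)
    m <- mem_slice(z) & pol$r_mm >= r_min_mm & pol$r_mm <= r_max_mm
    sec <- sector_of(pol$theta_deg, convention)
    cnt <- volume[, , z]
    raw[i, ] <- vapply(seq_len(n_sec),
                       function(k) sum(cnt[m & sec == k]), numeric(1))
  }
  total <- sum(raw)
  if (total <= 0) abort("no counts in the analyzed segments")

  grid <- tibble(
    slice = rep(seq_along(slices), each = n_sec),
    z_index = rep(slices, each = n_sec),
    sector = rep(seq_len(n_sec), length(slices)),
    sector_center_deg = rep(sector_centers(convention), length(slices)),
    raw_counts = as.vector(t(raw)),
    value = as.vector(t(raw)) / total
  )
  attr(grid, "total_counts") <- total
  attr(grid, "convention") <- convention
  class(grid) <- c("sector_grid", class(grid))
  grid
}

#' Sectorize both volumes of a study with shared geometry
#'
#' Applies [select_slices()] and myocardium membership on the AC volume, then
#' sectorizes NAC and AC about one shared in-plane centre -- the
#' paired-geometry contract that makes the per-segment NAC/AC ratio
#' meaningful.
#'
#' The shared centre is the count-weighted centroid of the AC counts over all
#' analyzed slices (the LV long-axis position of a reoriented short-axis
#' stack), snapped to the half-voxel grid. The snap makes sector assignment
#' robust to sub-voxel centroid jitter from counting noise or small perfusion
#' defects, which would otherwise reshuffle boundary voxels between sectors.
#' Per-slice centres (see [slice_centers()]) can still be passed explicitly
#' through `...` via [sectorize()] for non-straight ventricles.
#'
#' @param x A `synthetic_study` (from [generate_study()]) or `study_bundle`
#'   (from [load_study()]).
#' @param convention [angular_convention()]; defaults to the study's own when
#'   it carries one.
#' @param ... Passed on to [sectorize()] (e.g. a radial band).
#' @return A list with elements `nac` and `ac`, each a `sector_grid`.
#' @export
sectorize_study <- function(x, convention = NULL, ...) {
  stopifnot(!is.null(x$ac), !is.null(x$nac), !is.null(x$profile))
  convention <- convention %||% x$convention %||% angular_convention()
  slices <- select_slices(x$ac, x$profile)
  per_slice <- slice_centers(x$ac, slices)
  w <- apply(x$ac, 3, sum)[slices]
  ctr <- colSums(per_slice * w) / sum(w)
  ctr <- round(2 * ctr) / 2  # snap to the half-voxel grid
  centers <- matrix(ctr, nrow = length(slices), ncol = 2, byrow = TRUE)
  list(
    nac = sectorize(x$nac, slices, centers, convention, membership = x$ac, ...),
    ac  = sectorize(x$ac, slices, centers, convention, membership = x$ac, ...)
  )
}
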