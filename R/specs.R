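#' Attenuation artifact specification
#'
#' A set of non-overlapping angular x axial zones, each with a multiplicative
#' transmission factor strictly in (0, 1). The simulator multiplies NAC voxel
#' counts inside each zone by its factor, emulating the count depression that
#' soft-tissue attenuation produces in the uncorrected image.
#'
#' Angular intervals are half-open `[angle_start_deg, angle_end_deg)` in the
#' package angular frame and may wrap through 360. Slice ranges are inclusive
#' and counted from the most basal myocardial slice (slice 1 = base).
#'
#' @param zones A data frame with columns `angle_start_deg`, `angle_end_deg`,
#'   `slice_start`, `slice_end`, `transmission`.
#' @return An object of class `artifact_spec` (a tibble of zones).
#' @seealso [sector_artifact()] for sector-aligned zones.
#' @export
artifact_spec <- function(zones) {
  zones <- as_tibble(zones)
  needed <- c("angle_start_deg", "angle_end_deg", "slice_start", "slice_end",
              "transmission")
  if (!all(needed %in% names(zones))) {
    abort(paste("artifact zones need columns:", paste(needed, collapse = ", ")))
  }
  if (nrow(zones) > 0) {
    if (!all(zones$transmission > 0 & zones$transmission < 1)) {
      abort("every transmission factor must lie strictly in (0, 1)")
    }
    if (!all(zones$slice_start >= 1 & zones$slice_end >= zones$slice_start)) {
      abort("slice ranges must satisfy 1 <= slice_start <= slice_end")
    }
    full <- zones$angle_end_deg - zones$angle_start_deg == 360
    span <- (zones$angle_end_deg - zones$angle_start_deg) %% 360
    if (any(span == 0 & !full)) {
      abort("zero-width angular interval in artifact zones")
    }
    if (zones_overlap(zones)) abort("artifact zones may not overlap")
  }
  class(zones) <- c("artifact_spec", class(zones))
  zones
}

#' Sector-aligned artifact zones
#'
#' Convenience constructor for the common case of an artifact occupying whole
#' 30-degree sectors over a basal slice range, one transmission factor per
#' sector.
#'
#' @param center_deg Sector centre angles (each of form 15 + 30 k in the
#'   default frame).
#' @param slice_start,slice_end Inclusive basal slice range (slice 1 = most
#'   basal myocardial slice).
#' @param transmission Transmission factor(s) in (0, 1), recycled against
#'   `center_deg`.
#' @param convention Angular convention; defines the sector span.
#' @return An [artifact_spec()] with one zone per sector.
#' @examples
#' # four inferolateral sectors over the 17 most basal slices
#' sector_artifact(c(105, 135, 165, 195), 1, 17, c(0.70, 0.70, 0.76, 0.76))
#' @export
sector_artifact <- function(center_deg, slice_start, slice_end, transmission,
                            convention = angular_convention()) {
  transmission <- rep_len(transmission, length(center_deg))
  half <- convention$sector_span_deg / 2
  artifact_spec(tibble(
    angle_start_deg = (center_deg - half) %% 360,
    angle_end_deg   = (center_deg + half) %% 360,
    slice_start = as.integer(slice_start),
    slice_end   = as.integer(slice_end),
    transmission = transmission
  ))
}

# TRUE when any two zones intersect (wrap-aware half-open angular intervals
# and inclusive slice ranges).
zones_overlap <- function(zones) {
  n <- nrow(zones)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      slices_meet <- zones$slice_start[i] <= zones$slice_end[j] &&
        zones$slice_start[j] <= zones$slice_end[i]
      if (!slices_meet) next
      if (arcs_intersect(zones$angle_start_deg[i], zones$angle_end_deg[i],
                         zones$angle_start_deg[j], zones$angle_end_deg[j])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Intersection of two half-open circular arcs [a1, b1) and [a2, b2).
# An end exactly 360 above its start denotes the full circle.
arcs_intersect <- function(a1, b1, a2, b2) {
  pieces <- function(a, b) {
    if (b - a == 360) return(list(c(0, 360)))
    a <- a %% 360; b <- b %% 360
    if (a < b) list(c(a, b)) else list(c(a, 360), c(0, b))
  }
  for (p in pieces(a1, b1)) {
    for (q in pieces(a2, b2)) {
      if (p[1] < q[2] && q[1] < p[2]) return(TRUE)
    }
  }
  FALSE
}

# Membership of angles (already in the convention frame) in [start, end).
in_arc <- function(theta_deg, start_deg, end_deg) {
  if (end_deg - start_deg == 360) return(rep(TRUE, length(theta_deg)))
  a <- start_deg %% 360
  b <- end_deg %% 360
  th <- theta_deg %% 360
  if (a < b) th >= a & th < b else th >= a | th < b
}

#' Solid perfusion defect specification
#'
#' A true perfusion defect: a compact region of the myocardial shell whose
#' uptake is scaled by `uptake_factor` in *both* the AC and NAC volumes. A true
#' defect is present regardless of attenuation correction, so it should leave
#' the NAC/AC ratio-based artifact delineation unchanged -- the control used to
#' separate artifact from disease.
#'
#' @param center_angle_deg Angular position of the defect centre (0 = anterior
#'   in the default frame).
#' @param axial_center_mm Axial position of the defect centre, mm from the
#'   basal end of the shell.
#' @param volume_cm3 Requested defect volume in cm^3 (> 0); the realized
#'   voxelized volume is within one voxel volume of this.
#' @param uptake_factor Residual uptake in `[0, 1)`; 0 gives a solid
#'   (cold) defect.
#' @return An object of class `defect_spec`.
#' @examples
#' defect_spec(center_angle_deg = 0, axial_center_mm = 40, volume_cm3 = 2.1)
#' @export
defect_spec <- function(center_angle_deg = 0, axial_center_mm, volume_cm3 = 2.1,
                        uptake_factor = 0) {
  stopifnot(volume_cm3 > 0)
  if (!(uptake_factor >= 0 && uptake_factor < 1)) {
    abort("uptake_factor must lie in [0, 1)")
  }
  structure(
    list(center_angle_deg = center_angle_deg %% 360,
         axial_center_mm = axial_center_mm,
         volume_cm3 = volume_cm3,
         uptake_factor = uptake_factor),
    class = "defect_spec"
  )
}

#' Simulated cohort specification
#'
#' Parameters of a simulated acquisition cohort. Per acquisition, the injected
#' artifact extent (% of segments) and depth (% residual counts, which sets the
#' transmission factor) are drawn from truncated normal distributions and the
#' artifact centre angle from a wrapped normal; the artifact is realized as a
#' contiguous sector-aligned angular block centred on the drawn angle.
#'
#' @param n_acquisitions Number of acquisitions (>= 2).
#' @param extent_mean_pct,extent_sd_pct Mean and SD of the injected extent in
#'   percent of segments; the draw is truncated to (0, 100).
#' @param depth_mean_pct,depth_sd_pct Mean and SD of the injected depth in
#'   percent; the draw is truncated to (1, 99) and divided by 100 to give the
#'   zone transmission factor.
#' @param angle_mean_deg,angle_sd_deg Mean and SD of the artifact centre angle
#'   in degrees (normal draw, wrapped to `[0, 360)`).
#' @param profile [camera_profile()] of the simulated acquisitions.
#' @param geometry [lv_geometry()] of the phantom.
#' @param noise Logical: apply Poisson counting noise to both volumes.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_acquisitions,
                        extent_mean_pct, extent_sd_pct,
                        depth_mean_pct, depth_sd_pct,
                        angle_mean_deg, angle_sd_deg,
                        profile, geometry = lv_geometry(),
                        noise = TRUE, seed = NULL) {
  n_acquisitions <- as.integer(n_acquisitions)
  stopifnot(n_acquisitions >= 2L,
            extent_sd_pct >= 0, depth_sd_pct >= 0, angle_sd_deg >= 0,
            inherits(profile, "camera_profile"),
            inherits(geometry, "lv_geometry"))
  if (!(extent_mean_pct > 0 && extent_mean_pct < 100) ||
      !(depth_mean_pct > 0 && depth_mean_pct < 100)) {
    abort("extent and depth means must lie in (0, 100) percent")
  }
  structure(
    list(n_acquisitions = n_acquisitions,
         extent_mean_pct = extent_mean_pct, extent_sd_pct = extent_sd_pct,
         depth_mean_pct = depth_mean_pct, depth_sd_pct = depth_sd_pct,
         angle_mean_deg = angle_mean_deg %% 360, angle_sd_deg = angle_sd_deg,
         profile = profile, geometry = geometry,
         noise = isTRUE(noise), seed = seed),
    class = "cohort_spec"
  )
}
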