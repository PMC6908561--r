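# Digital LV phantom: noiseless AC volume builder, multiplicative attenuation
# zones on the NAC copy, solid defects applied to both volumes, Poisson noise,
# and the end-to-end study generator with full ground-truth bookkeeping.

#' Build the noiseless attenuation-corrected phantom volume
#'
#' Voxelizes the myocardial shell of an [lv_geometry()] onto the isotropic grid
#' of a [camera_profile()]. The shell is centred in-plane on the grid centre;
#' slice 1 of the returned array is the most basal end (after an empty margin).
#'
#' By default expected counts are *sector-equalized*: within each slice, every
#' voxel is weighted by (mean sector voxel count / its sector's voxel count) so
#' that all twelve 30-degree sectors carry exactly equal expected counts. A
#' binary voxelization of an annulus on a square grid does not have this
#' property, and without it noiseless fixtures would not be analytically exact.
#' Total expected counts remain `count_density` times the number of shell
#' voxels. Set `equalize_sectors = FALSE` for plain binary membership.
#'
#' @param geometry An [lv_geometry()].
#' @param profile A [camera_profile()]; sets the voxel size.
#' @param margin_voxels Empty margin added on every side of the shell.
#' @param equalize_sectors Equalize expected counts across sectors (default
#'   `TRUE`; see Details).
#' @param convention [angular_convention()] used for the equalization sectors.
#' @return A 3-D numeric array of expected counts with attributes
#'   `voxel_size_mm` and `center` (in-plane centre, voxel coordinates).
#'   Dimension order is (x, y, z) with z running base -> apex.
#' @examples
#' vol <- build_ac_volume(lv_geometry(), camera_profile("czt"))
#' dim(vol)
#' @export
build_ac_volume <- function(geometry, profile, margin_voxels = 2,
                            equalize_sectors = TRUE,
                            convention = angular_convention()) {
  stopifnot(inherits(geometry, "lv_geometry"),
            inherits(profile, "camera_profile"))
  vox <- profile$voxel_size_mm
  n_ax <- round(geometry$axial_length_mm / vox)
  if (n_ax < profile$n_slices) {
    abort(sprintf(
      "geometry too short for profile: %d shell slices < %d analyzed slices",
      n_ax, profile$n_slices))
  }
  n_cap <- if (geometry$shape == "cylinder_capped") {
    floor(geometry$outer_radius_mm / vox)
  } else 0L
  n_xy <- 2L * ceiling(geometry$outer_radius_mm / vox) + 2L * margin_voxels
  nz <- n_ax + n_cap + 2L * margin_voxels
  cx <- (n_xy + 1) / 2
  pol <- polar_grid(n_xy, n_xy, c(cx, cx), vox, convention)

  vol <- array(0, dim = c(n_xy, n_xy, nz))
  r_out <- geometry$outer_radius_mm
  r_in <- r_out - geometry$wall_thickness_mm

  slice_pattern <- function(ro, ri) {
    member <- pol$r_mm <= ro & pol$r_mm > ri
    if (!any(member)) return(NULL)
    vals <- matrix(0, n_xy, n_xy)
    if (equalize_sectors) {
      sec <- sector_of(pol$theta_deg, convention)
      n_k <- tabulate(sec[member], nbins = convention$n_sectors)
      present <- n_k > 0
      w <- rep(0, convention$n_sectors)
      w[present] <- mean(n_k[present]) / n_k[present]
      vals[member] <- geometry$count_density * w[sec[member]]
    } else {
      vals[member] <- geometry$count_density
    }
    vals
  }

  cyl <- slice_pattern(r_out, r_in)
  if (is.null(cyl)) abort("shell geometry produces no voxels at this resolution")
  for (z in seq_len(n_ax)) vol[, , margin_voxels + z] <- cyl
  if (n_cap > 0) {
    for (j in seq_len(n_cap)) {
      d <- (j - 0.5) * vox
      ro <- sqrt(max(r_out^2 - d^2, 0))
      ri <- sqrt(max(r_in^2 - d^2, 0))
      cap <- slice_pattern(ro, ri)
      if (!is.null(cap)) vol[, , margin_voxels + n_ax + j] <- cap
    }
  }
  attr(vol, "voxel_size_mm") <- vox
  attr(vol, "center") <- c(cx, cx)
  vol
}

#' Apply attenuation artifact zones to produce the NAC volume
#'
#' Multiplies voxel counts inside each zone of an [artifact_spec()] by that
#' zone's transmission factor, leaving all other voxels (and the AC input)
#' untouched. Voxel zone membership uses the angle of the voxel centre about
#' the in-plane shell centre, under the same half-open binning rule as
#' sectorization, so sector-aligned zones depress whole segments exactly.
#'
#' Zone slice ranges are counted from the most basal slice with any counts.
#'
#' @param ac_volume Noiseless AC volume from [build_ac_volume()] (or any
#'   non-negative count array with `voxel_size_mm`/`center` attributes).
#' @param spec An [artifact_spec()]; an empty spec returns the input unchanged.
#' @param convention [angular_convention()] in which the zone angles are
#'   expressed.
#' @return The NAC volume (same shape and attributes as the input).
#' @export
apply_artifact <- function(ac_volume, spec, convention = angular_convention()) {
  spec <- artifact_spec(spec)  # revalidates (factors in range, no overlap)
  nac <- ac_volume
  if (nrow(spec) == 0) return(nac)
  mask_info <- artifact_voxel_zones(ac_volume, spec, convention)
  for (i in seq_len(nrow(spec))) {
    idx <- mask_info$zone_voxels[[i]]
    nac[idx] <- nac[idx] * spec$transmission[i]
  }
  nac
}

# Voxel membership of each zone: returns list(zone_voxels = list of linear
# index vectors, basal_slice). Shared by apply_artifact and truth bookkeeping.
artifact_voxel_zones <- function(volume, spec, convention) {
  d <- dim(volume)
  vox <- attr(volume, "voxel_size_mm") %||% 1
  ctr <- attr(volume, "center") %||% c((d[1] + 1) / 2, (d[2] + 1) / 2)
  pol <- polar_grid(d[1], d[2], ctr, vox, convention)
  slice_sums <- apply(volume, 3, sum)
  nonzero <- which(slice_sums > 0)
  if (length(nonzero) == 0) abort("volume has no counts")
  basal <- nonzero[1]
  zone_voxels <- vector("list", nrow(spec))
  n_xy <- d[1] * d[2]
  for (i in seq_len(nrow(spec))) {
    z_lo <- basal + spec$slice_start[i] - 1L
    z_hi <- basal + spec$slice_end[i] - 1L
    if (z_hi > d[3]) abort("artifact zone slice range exceeds the volume")
    arc <- which(in_arc(pol$theta_deg, spec$angle_start_deg[i],
                        spec$angle_end_deg[i]))
    zone_voxels[[i]] <- as.vector(outer(arc, (z_lo:z_hi - 1L) * n_xy, `+`))
  }
  list(zone_voxels = zone_voxels, basal_slice = basal)
}

#' Insert a solid perfusion defect into both volumes
#'
#' Scales the same compact set of myocardial voxels by the defect's uptake
#' factor in *both* the AC and NAC volumes, emulating a true perfusion defect
#' that exists regardless of attenuation correction. Voxels are chosen by a
#' greedy nearest-voxel fill of the shell around the requested centre until the
#' requested volume is reached; the realized voxel volume is reported and is
#' within one voxel volume of the request (unless clipped by the shell, which
#' warns).
#'
#' @param ac_volume,nac_volume Paired count volumes (identical shape).
#' @param defect A [defect_spec()].
#' @param geometry The [lv_geometry()] the volumes were built from (sets the
#'   mid-wall radius at which the defect centre is placed).
#' @param convention [angular_convention()] for the defect centre angle.
#' @return A list with elements `ac`, `nac`, `defect_mask` (logical array),
#'   `realized_volume_cm3`, `requested_volume_cm3`.
#' @export
insert_defect <- function(ac_volume, nac_volume, defect, geometry,
                          convention = angular_convention()) {
  stopifnot(inherits(defect, "defect_spec"),
            identical(dim(ac_volume), dim(nac_volume)))
  d <- dim(ac_volume)
  vox <- attr(ac_volume, "voxel_size_mm") %||% 1
  ctr <- attr(ac_volume, "center") %||% c((d[1] + 1) / 2, (d[2] + 1) / 2)

  shell <- which(ac_volume > 0, arr.ind = TRUE)
  if (nrow(shell) == 0) abort("no myocardial voxels to place a defect in")
  basal <- min(shell[, 3])

  # defect centre in voxel coordinates; anterior = +y in the image frame
  r_mid <- geometry$outer_radius_mm - geometry$wall_thickness_mm / 2
  th <- (defect$center_angle_deg + convention$rotation_deg) * pi / 180
  cx <- ctr[1] + r_mid * sin(th) / vox
  cy <- ctr[2] + r_mid * cos(th) / vox
  cz <- basal + defect$axial_center_mm / vox - 0.5

  n_req <- max(1L, round(defect$volume_cm3 * 1000 / vox^3))
  dist2 <- (shell[, 1] - cx)^2 + (shell[, 2] - cy)^2 + (shell[, 3] - cz)^2
  ord <- order(dist2, shell[, 3], shell[, 2], shell[, 1])
  if (n_req > nrow(shell)) {
    warn(sprintf("defect of %.2f cm^3 exceeds the shell: clipped to %d voxels",
                 defect$volume_cm3, nrow(shell)))
    n_req <- nrow(shell)
  }
  chosen <- shell[ord[seq_len(n_req)], , drop = FALSE]
  mask <- array(FALSE, dim = d)
  mask[chosen] <- TRUE

  ac <- ac_volume; nac <- nac_volume
  ac[mask] <- ac[mask] * defect$uptake_factor
  nac[mask] <- nac[mask] * defect$uptake_factor
  list(ac = ac, nac = nac, defect_mask = mask,
       realized_volume_cm3 = n_req * vox^3 / 1000,
       requested_volume_cm3 = defect$volume_cm3)
}

#' Add Poisson counting noise to a volume
#'
#' Replaces each voxel's expected count by an independent Poisson draw with
#' that mean. Zero-expectation voxels stay exactly zero.
#'
#' @param volume Non-negative array of expected counts.
#' @param seed Optional integer seed; given the same seed the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A volume of the same shape and attributes with integer counts.
#' @export
add_poisson_noise <- function(volume, seed = NULL) {
  if (any(volume < 0)) abort("expected counts must be non-negative")
  draw <- function() {
    out <- volume
    out[] <- rpois(length(volume), lambda = as.numeric(volume))
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a complete synthetic NAC/AC study
#'
#' Composes [build_ac_volume()] -> [insert_defect()] -> [apply_artifact()] ->
#' optional independent Poisson noise on both volumes, recording all ground
#' truth (voxel-level artifact and defect masks, per-zone transmission factors,
#' and -- for sector-aligned zones -- the per-segment truth mask over the
#' analyzed grid).
#'
#' @param profile A [camera_profile()].
#' @param geometry An [lv_geometry()].
#' @param artifact An [artifact_spec()] or `NULL` for no artifact.
#' @param defect A [defect_spec()] or `NULL`.
#' @param noise Logical: Poisson noise on both volumes (independent draws).
#' @param seed Integer seed for the noise; with `noise = FALSE` the study is
#'   deterministic and `seed` is only recorded.
#' @param convention [angular_convention()].
#' @return An object of class `synthetic_study`: a list with `ac`, `nac`
#'   (count arrays), `profile`, `geometry`, `convention`, `artifact`, `defect`,
#'   `noise`, `seed`, and `truth` (list: `segment_mask` tibble or `NULL`,
#'   `artifact_voxel_mask`, `defect_mask`, `realized_defect_cm3`).
#' @examples
#' study <- generate_study(camera_profile("czt"),
#'                         artifact = sector_artifact(165, 1, 17, 0.7))
#' study
#' @export
generate_study <- function(profile, geometry = lv_geometry(), artifact = NULL,
                           defect = NULL, noise = FALSE, seed = NULL,
                           convention = angular_convention()) {
  ac <- build_ac_volume(geometry, profile, convention = convention)

  defect_mask <- NULL
  realized_cm3 <- NULL
  if (!is.null(defect)) {
    res <- insert_defect(ac, ac, defect, geometry, convention)
    ac <- res$ac
    defect_mask <- res$defect_mask
    realized_cm3 <- res$realized_volume_cm3
  }

  artifact_voxel_mask <- NULL
  segment_truth <- NULL
  if (!is.null(artifact) && nrow(artifact) > 0) {
    artifact <- artifact_spec(artifact)
    nac <- apply_artifact(ac, artifact, convention)
    zv <- artifact_voxel_zones(ac, artifact, convention)
    artifact_voxel_mask <- array(FALSE, dim = dim(ac))
    for (idx in zv$zone_voxels) artifact_voxel_mask[idx] <- TRUE
    artifact_voxel_mask <- artifact_voxel_mask & ac > 0
    segment_truth <- segment_truth_mask(artifact, profile, convention)
  } else {
    nac <- ac
  }

  if (isTRUE(noise)) {
    noisy <- function() list(nac = add_poisson_noise(nac),
                             ac = add_poisson_noise(ac))
    both <- if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
    nac <- both$nac
    ac <- both$ac
  }

  structure(
    list(ac = ac, nac = nac, profile = profile, geometry = geometry,
         convention = convention, artifact = artifact, defect = defect,
         noise = isTRUE(noise), seed = seed,
         truth = list(segment_mask = segment_truth,
                      artifact_voxel_mask = artifact_voxel_mask,
                      defect_mask = defect_mask,
                      realized_defect_cm3 = realized_cm3)),
    class = "synthetic_study"
  )
}

# Per-segment truth over the analyzed grid, when every zone is sector-aligned
# (boundaries on multiples of the sector span); otherwise NULL.
segment_truth_mask <- function(spec, profile, convention) {
  span <- convention$sector_span_deg
  aligned <- all(abs((spec$angle_start_deg %% span)) < 1e-8 |
                   abs((spec$angle_start_deg %% span) - span) < 1e-8) &&
    all(abs((spec$angle_end_deg %% span)) < 1e-8 |
          abs((spec$angle_end_deg %% span) - span) < 1e-8)
  if (!aligned) return(NULL)
  centers <- sector_centers(convention)
  grid <- tidyr::expand_grid(slice = seq_len(profile$n_slices),
                             sector = seq_len(convention$n_sectors))
  grid$sector_center_deg <- centers[grid$sector]
  grid$attenuated <- FALSE
  grid$transmission <- NA_real_
  for (i in seq_len(nrow(spec))) {
    hit <- in_arc(grid$sector_center_deg, spec$angle_start_deg[i],
                  spec$angle_end_deg[i]) &
      grid$slice >= spec$slice_start[i] & grid$slice <= spec$slice_end[i]
    grid$attenuated[hit] <- TRUE
    grid$transmission[hit] <- spec$transmission[i]
  }
  grid
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %s profile, %s, %s, noise %s%s>\n",
              x$profile$name,
              if (is.null(x$artifact) || nrow(x$artifact) == 0) "no artifact"
              else sprintf("%d artifact zone(s)", nrow(x$artifact)),
              if (is.null(x$defect)) "no defect"
              else sprintf("%.2f cm^3 defect", x$defect$volume_cm3),
              if (x$noise) "on" else "off",
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  volumes %s, voxel %g mm\n",
              paste(dim(x$ac), collapse = "x"),
              attr(x$ac, "voxel_size_mm")))
  invisible(x)
}
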