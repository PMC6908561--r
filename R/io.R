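# Study input/output: NIfTI volumes with a JSON sidecar for camera metadata
# and synthetic ground truth, CSV sector tables, and JSON metric reports.
# All schemas carry a format_version field.

FORMAT_VERSION <- "1.0"

#' Write a study to disk
#'
#' Writes the NAC and AC volumes as NIfTI (`.nii.gz`, isotropic voxel size in
#' the header) plus a JSON sidecar carrying the camera profile, angular
#' convention, seed, noise flag and -- for synthetic studies -- the injected
#' truth (zones, defect, realized defect volume).
#'
#' @param study A `synthetic_study` or `study_bundle`.
#' @param dir Output directory (created if needed).
#' @param name File stem; writes `<name>_nac.nii.gz`, `<name>_ac.nii.gz`,
#'   `<name>_sidecar.json`.
#' @return Invisibly, the three paths (named `nac`, `ac`, `sidecar`).
#' @export
write_study <- function(study, dir, name = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- attr(study$ac, "voxel_size_mm") %||% study$profile$voxel_size_mm
  paths <- c(nac = file.path(dir, paste0(name, "_nac.nii.gz")),
             ac = file.path(dir, paste0(name, "_ac.nii.gz")),
             sidecar = file.path(dir, paste0(name, "_sidecar.json")))
  write_vol <- function(v, p) {
    img <- RNifti::asNifti(array(as.numeric(v), dim = dim(v)))
    RNifti::pixdim(img) <- rep(vox, 3)
    RNifti::writeNifti(img, p)
  }
  write_vol(study$nac, paths[["nac"]])
  write_vol(study$ac, paths[["ac"]])

  sidecar <- list(
    format_version = FORMAT_VERSION,
    package_version = as.character(packageVersion("attenquant")),
    profile = study$profile[c("name", "voxel_size_mm", "n_slices",
                              "ratio_threshold")],
    convention = list(rotation_deg =
                        (study$convention %||% angular_convention())$rotation_deg),
    seed = study$seed,
    noise = isTRUE(study$noise)
  )
  if (!is.null(study$artifact) && NROW(study$artifact) > 0) {
    sidecar$truth_zones <- as.data.frame(study$artifact)
  }
  if (!is.null(study$defect)) {
    sidecar$truth_defect <- unclass(study$defect)
    sidecar$realized_defect_cm3 <- study$truth$realized_defect_cm3
  }
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' Load a paired NAC/AC study from disk
#'
#' Reads the two NIfTI volumes and, when present, the JSON sidecar. The pair
#' must have identical shapes and identical isotropic voxel sizes;
#' non-isotropic volumes are rejected (the pipeline assumes isotropic voxels).
#' Without a sidecar the camera profile must be supplied.
#'
#' @param nac_path,ac_path Paths to the NAC and AC NIfTI volumes.
#' @param sidecar_path Optional path to the JSON sidecar.
#' @param profile Optional [camera_profile()] overriding / replacing the
#'   sidecar's.
#' @return An object of class `study_bundle`: list with `nac`, `ac` (count
#'   arrays with `voxel_size_mm` attributes), `profile`, `provenance` (sidecar
#'   contents or `NULL`).
#' @export
load_study <- function(nac_path, ac_path, sidecar_path = NULL, profile = NULL) {
  read_vol <- function(p) {
    if (!file.exists(p)) abort(paste("no such file:", p))
    img <- RNifti::readNifti(p)
    pd <- RNifti::pixdim(img)[seq_len(3)]
    if (diff(range(pd)) > 1e-6 * mean(pd)) {
      abort(sprintf("%s has non-isotropic voxels (%s); the pipeline requires isotropic volumes",
                    p, paste(signif(pd, 4), collapse = " x ")))
    }
    v <- array(as.numeric(img), dim = dim(img))
    attr(v, "voxel_size_mm") <- pd[1]
    v
  }
  nac <- read_vol(nac_path)
  ac <- read_vol(ac_path)
  if (!identical(dim(nac), dim(ac))) {
    abort(sprintf("NAC and AC volume shapes differ: %s vs %s",
                  paste(dim(nac), collapse = "x"),
                  paste(dim(ac), collapse = "x")))
  }
  if (abs(attr(nac, "voxel_size_mm") - attr(ac, "voxel_size_mm")) > 1e-6) {
    abort("NAC and AC voxel sizes differ")
  }

  provenance <- NULL
  if (!is.null(sidecar_path)) {
    provenance <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (is.null(profile) && !is.null(provenance$profile)) {
      p <- provenance$profile
      profile <- camera_profile(p$name, p$voxel_size_mm, p$n_slices,
                                p$ratio_threshold)
    }
  }
  if (is.null(profile)) {
    abort("no sidecar profile available: supply `profile`")
  }
  if (abs(profile$voxel_size_mm - attr(ac, "voxel_size_mm")) > 1e-6) {
    abort(sprintf("profile voxel size %g mm does not match volume headers (%g mm)",
                  profile$voxel_size_mm, attr(ac, "voxel_size_mm")))
  }
  structure(list(nac = nac, ac = ac, profile = profile,
                 provenance = provenance),
            class = "study_bundle")
}

#' Write a sector table as CSV
#'
#' One row per analyzed segment with its normalized counts (the segment counts
#' divided by the grand total over all analyzed segments).
#'
#' @param grid A `sector_grid` from [sectorize()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sector_table <- function(grid, path) {
  out <- data.frame(slice_index = grid$slice,
                    sector_index = grid$sector,
                    sector_center_deg = grid$sector_center_deg,
                    normalized_counts = grid$value)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a sector table written by [write_sector_table()]
#'
#' @param path CSV path.
#' @return A tibble with the four sector-table columns.
#' @export
read_sector_table <- function(path) {
  as_tibble(read.csv(path))
}

#' Write artifact metrics as JSON
#'
#' Serializes an `artifact_metrics` object: extent as fraction and rounded
#' percent, localization angle (null when undefined), depth as fraction and
#' rounded percent, the threshold used and the segment counts.
#'
#' @param metrics An `artifact_metrics` from [quantify_study()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(metrics, path) {
  payload <- list(
    format_version = FORMAT_VERSION,
    package_version = as.character(packageVersion("attenquant")),
    profile = metrics$profile,
    threshold_used = metrics$threshold_used,
    extent_fraction = metrics$extent_fraction,
    extent_pct_rounded = metrics$extent_pct,
    localization_deg = if (is.na(metrics$localization_deg)) NULL
                       else metrics$localization_deg,
    depth_fraction = if (is.na(metrics$depth_fraction)) NULL
                     else metrics$depth_fraction,
    depth_pct_rounded = if (is.na(metrics$depth_fraction)) NULL
                        else metrics$depth_pct,
    n_artifact_segments = metrics$n_artifact_segments,
    n_total_segments = metrics$n_total_segments,
    options = metrics$options
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a metrics JSON written by [write_metrics()]
#'
#' @param path JSON path.
#' @return A list of the stored fields (`localization_deg` / `depth_fraction`
#'   are `NULL` when they were undefined).
#' @export
read_metrics <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
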