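#' Camera acquisition profile
#'
#' Bundles the per-camera constants the pipeline depends on: the isotropic
#' voxel size of the reconstructed short-axis volume, the number of analyzed
#' short-axis slices (counted from the base), and the NAC/AC ratio threshold
#' below which a segment is delineated as attenuation artifact.
#'
#' Two profiles are built in:
#' \describe{
#'   \item{`"czt"`}{dedicated cardiac CZT camera: 4 mm voxels, 20 slices,
#'     threshold 0.90.}
#'   \item{`"ventri"`}{conventional dual-head NaI camera: 6.4 mm voxels,
#'     12 slices, threshold 0.85.}
#' }
#' Custom profiles are created by supplying all fields.
#'
#' @param name Profile name. `"czt"` or `"ventri"` select the built-ins;
#'   any other name requires the remaining arguments.
#' @param voxel_size_mm Isotropic voxel edge length in mm (> 0).
#' @param n_slices Number of analyzed short-axis slices (>= 1).
#' @param ratio_threshold Delineation threshold on the NAC/AC ratio, strictly
#'   in (0, 1).
#' @return An object of class `camera_profile`.
#' @examples
#' camera_profile("czt")
#' camera_profile("toy", voxel_size_mm = 5, n_slices = 8, ratio_threshold = 0.9)
#' @export
camera_profile <- function(name, voxel_size_mm = NULL, n_slices = NULL,
                           ratio_threshold = NULL) {
  builtin <- list(
    czt    = list(voxel_size_mm = 4.0, n_slices = 20L, ratio_threshold = 0.90),
    ventri = list(voxel_size_mm = 6.4, n_slices = 12L, ratio_threshold = 0.85)
  )
  if (name %in% names(builtin)) {
    b <- builtin[[name]]
    voxel_size_mm   <- voxel_size_mm %||% b$voxel_size_mm
    n_slices        <- n_slices %||% b$n_slices
    ratio_threshold <- ratio_threshold %||% b$ratio_threshold
  }
  if (is.null(voxel_size_mm) || is.null(n_slices) || is.null(ratio_threshold)) {
    abort(paste0("unknown camera profile '", name,
                 "': supply voxel_size_mm, n_slices and ratio_threshold"))
  }
  stopifnot(is.numeric(voxel_size_mm), voxel_size_mm > 0)
  n_slices <- as.integer(n_slices)
  stopifnot(n_slices >= 1L)
  if (!(ratio_threshold > 0 && ratio_threshold < 1)) {
    abort("ratio_threshold must lie strictly in (0, 1)")
  }
  structure(
    list(name = name, voxel_size_mm = voxel_size_mm, n_slices = n_slices,
         ratio_threshold = ratio_threshold),
    class = "camera_profile"
  )
}

#' @export
print.camera_profile <- function(x, ...) {
  cat(sprintf(
    "<camera_profile '%s': %g mm voxels, %d analyzed slices, ratio threshold %.2f>\n",
    x$name, x$voxel_size_mm, x$n_slices, x$ratio_threshold))
  invisible(x)
}

#' Angular convention of the short-axis sectorization
#'
#' Defines the angular reference frame of the 12-sector ring: 0 degrees at the
#' anterior wall, angles increasing anterior -> lateral (90) -> inferior (180)
#' -> septal (270). Sector `i` covers the half-open bin
#' `[30 (i - 1), 30 i)` with its centre at `30 (i - 1) + 15` degrees.
#'
#' `rotation_deg` rotates the frame relative to the image axes, for data whose
#' anatomical orientation differs from the package default (anterior along the
#' +y image axis, lateral along +x).
#'
#' @param rotation_deg Rotation of the reference frame relative to the image
#'   axes, degrees.
#' @return An object of class `angular_convention`.
#' @export
angular_convention <- function(rotation_deg = 0) {
  stopifnot(is.numeric(rotation_deg), length(rotation_deg) == 1L)
  structure(
    list(zero_direction = "anterior",
         rotation_sense = "anterior -> lateral -> inferior -> septal",
         sector_span_deg = 30,
         n_sectors = 12L,
         rotation_deg = rotation_deg %% 360),
    class = "angular_convention"
  )
}

#' Sector centre angles under a convention
#'
#' @param convention An [angular_convention()].
#' @return Numeric vector of the 12 sector centre angles in degrees
#'   (15, 45, ..., 345 in the default frame).
#' @export
sector_centers <- function(convention = angular_convention()) {
  (seq_len(convention$n_sectors) - 1) * convention$sector_span_deg +
    convention$sector_span_deg / 2
}

# Sector index (1..12) of an angle already expressed in the convention frame.
sector_of <- function(theta_deg, convention = angular_convention()) {
  pmin(floor((theta_deg %% 360) / convention$sector_span_deg) + 1L,
       convention$n_sectors)
}
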