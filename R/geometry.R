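#' Left-ventricular phantom geometry
#'
#' Describes the digital myocardial phantom: a cylindrical shell (optionally
#' closed apically by a hemispherical cap) of uniform expected count density,
#' modeled on a commercial cardiac insert. The analyzed axial span is the
#' uniform cylindrical part, so that every analyzed segment carries the same
#' expected counts; the cap, when present, adds apical slices beyond the
#' analyzed range.
#'
#' @param outer_radius_mm Outer radius of the myocardial shell, mm.
#' @param wall_thickness_mm Myocardial wall thickness, mm; must be smaller
#'   than `outer_radius_mm`.
#' @param axial_length_mm Axial length of the cylindrical part, mm. Must cover
#'   at least `n_slices * voxel_size_mm` of the camera profile it is imaged
#'   with (checked at volume build time).
#' @param shape `"cylinder"` for an open shell, `"cylinder_capped"` to add a
#'   hemispherical apical cap.
#' @param count_density Expected counts per myocardial voxel (> 0). The
#'   per-voxel expectation in the noiseless volume; Poisson noise, when
#'   enabled, draws around it.
#' @return An object of class `lv_geometry`.
#' @examples
#' lv_geometry()
#' lv_geometry(outer_radius_mm = 35, wall_thickness_mm = 12)
#' @export
lv_geometry <- function(outer_radius_mm = 30, wall_thickness_mm = 10,
                        axial_length_mm = 96,
                        shape = c("cylinder", "cylinder_capped"),
                        count_density = 500) {
  shape <- match.arg(shape)
  stopifnot(outer_radius_mm > 0, axial_length_mm > 0, count_density > 0)
  if (!(wall_thickness_mm > 0 && wall_thickness_mm < outer_radius_mm)) {
    abort("wall_thickness_mm must lie strictly in (0, outer_radius_mm)")
  }
  structure(
    list(outer_radius_mm = outer_radius_mm,
         wall_thickness_mm = wall_thickness_mm,
         axial_length_mm = axial_length_mm,
         shape = shape,
         count_density = count_density),
    class = "lv_geometry"
  )
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf(
    "<lv_geometry: %s, outer radius %g mm, wall %g mm, length %g mm, density %g counts/voxel>\n",
    x$shape, x$outer_radius_mm, x$wall_thickness_mm, x$axial_length_mm,
    x$count_density))
  invisible(x)
}
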