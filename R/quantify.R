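# NAC/AC ratio map, threshold delineation, and the three artifact metrics:
# extent (fraction of segments), localization (circular mean angle) and depth
# (count level in the artifact relative to the brightest 30% of segments).

#' Per-segment NAC/AC ratio map
#'
#' The ratio of normalized NAC to normalized AC counts per (slice, sector)
#' segment -- the descriptor of the attenuation artifact. Segments without
#' attenuation sit at the common renormalization level (slightly above 1, since
#' the artifact removes counts from the NAC total); attenuated segments fall
#' below it. Segments with zero AC counts are flagged undefined rather than
#' infinite and can never join the artifact mask.
#'
#' @param nac_grid,ac_grid `sector_grid`s of the same study built with shared
#'   geometry (see [sectorize_study()]).
#' @return A `ratio_map` tibble: `slice`, `sector`, `sector_center_deg`,
#'   `nac_value`, `ac_value`, `ratio`, `defined`.
#' @export
compute_ratio <- function(nac_grid, ac_grid) {
  if (nrow(nac_grid) != nrow(ac_grid) ||
      !identical(nac_grid$slice, ac_grid$slice) ||
      !identical(nac_grid$sector, ac_grid$sector) ||
      !isTRUE(all.equal(nac_grid$sector_center_deg, ac_grid$sector_center_deg))) {
    abort("NAC and AC sector grids do not share shape and angular convention")
  }
  out <- tibble(
    slice = nac_grid$slice,
    sector = nac_grid$sector,
    sector_center_deg = nac_grid$sector_center_deg,
    nac_value = nac_grid$value,
    ac_value = ac_grid$value,
    defined = ac_grid$raw_counts > 0
  )
  out$ratio <- ifelse(out$defined, out$nac_value / out$ac_value, NA_real_)
  class(out) <- c("ratio_map", class(out))
  out
}

#' Delineate the attenuation artifact by ratio threshold
#'
#' Marks as artifact every defined segment whose NAC/AC ratio is strictly
#' below the threshold. No connectivity filtering is applied by default: the
#' delineation is a pure threshold. Optionally (`connectivity = TRUE`) only
#' the largest 4-connected component on the slice x sector grid (with angular
#' wrap) is kept.
#'
#' @param ratio A `ratio_map` from [compute_ratio()].
#' @param threshold Ratio threshold strictly in (0, 1), e.g. the camera
#'   profile's (0.90 CZT, 0.85 conventional).
#' @param connectivity Keep only the largest connected artifact component.
#' @return An `artifact_mask` tibble: the ratio map plus a logical `artifact`
#'   column, with attribute `threshold_used`.
#' @export
delineate <- function(ratio, threshold, connectivity = FALSE) {
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold < 1)) {
    abort("threshold must be a single number strictly in (0, 1)")
  }
  out <- ratio
  out$artifact <- out$defined & !is.na(out$ratio) & out$ratio < threshold
  if (isTRUE(connectivity) && any(out$artifact)) {
    out$artifact <- largest_component(out)
  }
  attr(out, "threshold_used") <- threshold
  class(out) <- unique(c("artifact_mask", class(out)))
  out
}

# Largest 4-connected artifact component on the (slice, sector) grid,
# sectors wrapping 12 -> 1. Flood fill over the marked segments.
largest_component <- function(mask_tbl) {
  n_slice <- max(mask_tbl$slice)
  n_sec <- max(mask_tbl$sector)
  m <- matrix(FALSE, n_slice, n_sec)
  m[cbind(mask_tbl$slice, mask_tbl$sector)] <- mask_tbl$artifact
  comp <- matrix(0L, n_slice, n_sec)
  next_id <- 0L
  for (s0 in seq_len(n_slice)) for (k0 in seq_len(n_sec)) {
    if (!m[s0, k0] || comp[s0, k0] > 0L) next
    next_id <- next_id + 1L
    queue <- list(c(s0, k0))
    comp[s0, k0] <- next_id
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      nb <- rbind(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                  c(p[1], (p[2] - 2) %% n_sec + 1),
                  c(p[1], p[2] %% n_sec + 1))
      for (r in seq_len(nrow(nb))) {
        s <- nb[r, 1]; k <- nb[r, 2]
        if (s >= 1 && s <= n_slice && m[s, k] && comp[s, k] == 0L) {
          comp[s, k] <- next_id
          queue <- c(queue, list(c(s, k)))
        }
      }
    }
  }
  keep <- which.max(tabulate(comp[comp > 0L]))
  comp[cbind(mask_tbl$slice, mask_tbl$sector)] == keep
}

#' Artifact extent
#'
#' Number of artifact segments divided by the total number of analyzed
#' segments.
#'
#' @param mask An `artifact_mask` from [delineate()].
#' @return Extent as a fraction in `[0, 1]`.
#' @export
artifact_extent <- function(mask) {
  sum(mask$artifact) / nrow(mask)
}

#' Artifact localization angle
#'
#' The angle of the artifact centre: the circular mean (mean resultant
#' direction) of the sector-centre angles of all artifact segments, each
#' segment weighted equally by default. With `weighted = TRUE` segments are
#' weighted by their depression `1 - ratio` instead.
#'
#' @param mask An `artifact_mask`.
#' @param weighted Weight segments by `1 - ratio`.
#' @return Angle in `[0, 360)` degrees, or `NA` (with a warning) for an empty
#'   mask or a zero resultant vector.
#' @export
artifact_localization <- function(mask, weighted = FALSE) {
  hit <- mask$artifact
  if (!any(hit)) {
    warn("empty artifact mask: localization undefined")
    return(NA_real_)
  }
  w <- if (isTRUE(weighted)) pmax(1 - mask$ratio[hit], 0) else NULL
  circ_mean_deg(mask$sector_center_deg[hit], w)
}

#' Artifact depth
#'
#' Mean normalized counts over the artifact segments divided by the mean over
#' the `round(top_fraction * n_total)` highest-count segments -- the residual
#' count level inside the artifact relative to the brightest part of the
#' myocardium (so smaller values mean deeper artifacts). Counts are taken from
#' the NAC grid by default (the attenuated image, where the reduction lives);
#' `source = "ac"` is available as a variant. Ties in the top-count ranking
#' are broken by segment position (slice, then sector), ascending.
#'
#' @param mask An `artifact_mask` (carries the per-segment NAC and AC values).
#' @param top_fraction Fraction of segments forming the reference maximum
#'   (default 0.30).
#' @param source `"nac"` or `"ac"`: which grid's counts to use.
#' @return Depth as a fraction (expected <= 1 for genuine artifacts), or `NA`
#'   (with a warning) for an empty mask.
#' @export
artifact_depth <- function(mask, top_fraction = 0.30, source = c("nac", "ac")) {
  source <- match.arg(source)
  vals <- if (source == "nac") mask$nac_value else mask$ac_value
  k <- round(top_fraction * nrow(mask))
  if (k < 1) abort("top_fraction selects no segments")
  if (!any(mask$artifact)) {
    warn("empty artifact mask: depth undefined")
    return(NA_real_)
  }
  ord <- order(-vals, mask$slice, mask$sector)
  mean(vals[mask$artifact]) / mean(vals[ord[seq_len(k)]])
}

#' Quantify the attenuation artifact of one study
#'
#' Runs the full pipeline on a paired NAC/AC study: basal slice selection,
#' shared centres and membership from the AC volume, sectorization of both
#' volumes, NAC/AC ratio map, threshold delineation at the camera profile's
#' threshold (or an override), and the three metrics.
#'
#' @param x A `synthetic_study` or `study_bundle`.
#' @param threshold Ratio threshold; defaults to the profile's.
#' @param weighted_localization Weight localization by depression depth.
#' @param depth_source `"nac"` (default) or `"ac"` counts for the depth.
#' @param top_fraction Reference fraction for the depth denominator.
#' @param connectivity Keep only the largest connected artifact component.
#' @param convention [angular_convention()]; defaults to the study's.
#' @return An object of class `artifact_metrics`: a list with
#'   `extent_fraction`, `extent_pct` (rounded), `localization_deg`,
#'   `depth_fraction`, `depth_pct` (rounded), `n_artifact_segments`,
#'   `n_total_segments`, `threshold_used`, `profile`, `options`, and the
#'   underlying `mask` (an `artifact_mask` tibble). Percentages are rounded to
#'   the nearest integer. `localization_deg` and `depth_fraction` are `NA`
#'   when the mask is empty.
#' @examples
#' study <- generate_study(camera_profile("czt"),
#'                         artifact = sector_artifact(c(135, 165), 1, 17, 0.7))
#' m <- quantify_study(study)
#' tidy(m)
#' @export
quantify_study <- function(x, threshold = NULL, weighted_localization = FALSE,
                           depth_source = "nac", top_fraction = 0.30,
                           connectivity = FALSE, convention = NULL) {
  grids <- sectorize_study(x, convention = convention)
  ratio <- compute_ratio(grids$nac, grids$ac)
  threshold <- threshold %||% x$profile$ratio_threshold
  mask <- delineate(ratio, threshold, connectivity = connectivity)

  empty <- !any(mask$artifact)
  loc <- if (empty) NA_real_ else
    artifact_localization(mask, weighted = weighted_localization)
  dep <- if (empty) NA_real_ else
    artifact_depth(mask, top_fraction = top_fraction, source = depth_source)

  structure(
    list(extent_fraction = artifact_extent(mask),
         extent_pct = round(100 * artifact_extent(mask)),
         localization_deg = loc,
         depth_fraction = dep,
         depth_pct = if (is.na(dep)) NA_real_ else round(100 * dep),
         n_artifact_segments = sum(mask$artifact),
         n_total_segments = nrow(mask),
         threshold_used = threshold,
         profile = x$profile$name,
         options = list(weighted_localization = weighted_localization,
                        depth_source = depth_source,
                        top_fraction = top_fraction,
                        connectivity = connectivity),
         mask = mask),
    class = "artifact_metrics"
  )
}

#' @export
print.artifact_metrics <- function(x, ...) {
  cat(sprintf("<artifact_metrics (%s, threshold %.2f)>\n",
              x$profile, x$threshold_used))
  cat(sprintf("  extent       %d/%d segments = %.1f%%\n",
              x$n_artifact_segments, x$n_total_segments,
              100 * x$extent_fraction))
  cat(sprintf("  localization %s\n",
              if (is.na(x$localization_deg)) "undefined (empty mask)"
              else sprintf("%.1f deg", x$localization_deg)))
  cat(sprintf("  depth        %s\n",
              if (is.na(x$depth_fraction)) "undefined (empty mask)"
              else sprintf("%.1f%% of the top-%d%% count level",
                           100 * x$depth_fraction,
                           round(100 * x$options$top_fraction))))
  invisible(x)
}
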