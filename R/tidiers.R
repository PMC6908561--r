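# broom-style tidiers for the package's result objects.

#' Tidy artifact metrics
#'
#' @param x An `artifact_metrics` from [quantify_study()].
#' @param ... Unused.
#' @return One-row tibble with the three metrics (fractions, rounded
#'   percentages and the localization angle) plus segment counts and the
#'   threshold used.
#' @method tidy artifact_metrics
#' @export
tidy.artifact_metrics <- function(x, ...) {
  tibble(
    extent_fraction = x$extent_fraction,
    extent_pct = x$extent_pct,
    localization_deg = x$localization_deg,
    depth_fraction = x$depth_fraction,
    depth_pct = x$depth_pct,
    n_artifact_segments = x$n_artifact_segments,
    n_total_segments = x$n_total_segments,
    threshold_used = x$threshold_used,
    profile = x$profile
  )
}

#' Glance at artifact metrics
#'
#' @param x An `artifact_metrics`.
#' @param ... Unused.
#' @return One-row tibble of the analysis settings (threshold, options,
#'   grid size).
#' @method glance artifact_metrics
#' @export
glance.artifact_metrics <- function(x, ...) {
  tibble(
    profile = x$profile,
    threshold_used = x$threshold_used,
    n_total_segments = x$n_total_segments,
    weighted_localization = x$options$weighted_localization,
    depth_source = x$options$depth_source,
    top_fraction = x$options$top_fraction,
    connectivity = x$options$connectivity
  )
}
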