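# Simulated acquisition cohorts: per-acquisition truth draws (extent, depth,
# centre angle), realization as sector-aligned contiguous angular blocks, and
# batch quantification.

# Truncated-normal draws by inverse CDF on the restricted uniform.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  qnorm(runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd)), mean, sd)
}

# Realize a drawn extent (m segments) and centre angle as a contiguous
# sector-aligned block: full sector columns over all analyzed slices plus a
# remainder column over the most basal slices, centred on the drawn angle.
cohort_zones <- function(m, center_angle_deg, transmission, profile,
                         convention = angular_convention()) {
  n_sec <- convention$n_sectors
  span <- convention$sector_span_deg
  n_slices <- profile$n_slices
  stopifnot(m >= 1, m <= n_sec * n_slices)
  full <- m %/% n_slices
  rem <- m %% n_slices
  width <- full + (rem > 0)
  # first column chosen so the block's angular centre is nearest the draw
  c0 <- (round((center_angle_deg - span / 2 * (width - 1) - span / 2) / span)
         %% n_sec) + 1
  cols <- ((c0 - 1) + seq_len(width) - 1) %% n_sec + 1
  zones <- tibble(
    angle_start_deg = (cols - 1) * span,
    angle_end_deg = cols * span,
    slice_start = 1L,
    slice_end = n_slices,
    transmission = transmission
  )
  if (rem > 0) zones$slice_end[width] <- rem
  artifact_spec(zones)
}

#' Draw the per-acquisition cohort truth
#'
#' The stochastic part of [generate_cohort()], separated so the statistical
#' chain can be exercised without building image volumes: per acquisition,
#' draws extent (% of segments, truncated normal on (0, 100)), depth
#' (% residual counts, truncated normal on (1, 99); the zone transmission
#' factor is depth/100), and centre angle (wrapped normal), converts the drawn
#' extent to the nearest achievable sector-aligned segment count, and assigns
#' each acquisition a study seed. Draws rounding to zero segments are redrawn
#' (bounded retries, with a message).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per acquisition: `acquisition`,
#'   `extent_drawn_pct`, `n_segments_injected`, `extent_injected_pct`,
#'   `depth_drawn_pct`, `transmission`, `angle_drawn_deg`, `study_seed`.
#' @export
draw_cohort_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$profile$n_slices * 12L
  draw_all <- function() {
    n <- spec$n_acquisitions
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      m <- 0L; tries <- 0L
      repeat {
        e <- rtruncnorm(1, spec$extent_mean_pct, spec$extent_sd_pct, 0, 100)
        m <- round(e / 100 * n_total)
        if (m >= 1L) break
        tries <- tries + 1L
        message(sprintf(
          "acquisition %d: drawn extent %.2f%% rounds to 0 segments; redrawing",
          i, e))
        if (tries >= 20L) abort("drawn extent repeatedly rounds to 0 segments")
      }
      d <- rtruncnorm(1, spec$depth_mean_pct, spec$depth_sd_pct, 1, 99)
      a <- rnorm(1, spec$angle_mean_deg, spec$angle_sd_deg) %% 360
      truth[[i]] <- tibble(
        acquisition = i,
        extent_drawn_pct = e,
        n_segments_injected = as.integer(m),
        extent_injected_pct = 100 * m / n_total,
        depth_drawn_pct = d,
        transmission = d / 100,
        angle_drawn_deg = a,
        study_seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
    }
    dplyr::bind_rows(truth)
  }
  if (is.null(spec$seed)) draw_all() else withr::with_seed(spec$seed, draw_all())
}

#' Generate a simulated acquisition cohort
#'
#' Draws per-acquisition truth from a [cohort_spec()] -- extent (% of segments,
#' truncated normal), depth (% residual counts, truncated normal; sets the
#' zone transmission factor), centre angle (wrapped normal) -- converts each
#' drawn extent to the nearest achievable sector-aligned segment count, builds
#' a contiguous angular block centred on the drawn angle, and generates the
#' corresponding [generate_study()] for each acquisition. Draws rounding to
#' zero segments are redrawn (at most 20 times each, with a message).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `studies` (list of
#'   `synthetic_study`), `truth` (tibble of drawn and realized truth per
#'   acquisition), and `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(4, 23, 5, 72, 0, 155, 17,
#'                                   camera_profile("czt"),
#'                                   noise = FALSE, seed = 7))
#' co$truth
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- draw_cohort_truth(spec)

  studies <- purrr::pmap(truth, function(acquisition, n_segments_injected,
                                         transmission, angle_drawn_deg,
                                         study_seed, ...) {
    zones <- cohort_zones(n_segments_injected, angle_drawn_deg, transmission,
                          spec$profile)
    generate_study(spec$profile, spec$geometry, artifact = zones,
                   noise = spec$noise, seed = study_seed)
  })

  structure(list(studies = studies, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d %s acquisitions, extent %g +/- %g%%, depth %g +/- %g%%, noise %s>\n",
    x$spec$n_acquisitions, x$spec$profile$name,
    x$spec$extent_mean_pct, x$spec$extent_sd_pct,
    x$spec$depth_mean_pct, x$spec$depth_sd_pct,
    if (x$spec$noise) "on" else "off"))
  invisible(x)
}

#' Quantify every acquisition of a cohort
#'
#' Runs [quantify_study()] on each acquisition and returns one row per
#' acquisition, with the injected truth joined alongside the recovered
#' metrics.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param ... Passed to [quantify_study()].
#' @return A tibble with the recovered `extent_fraction`, `extent_pct`,
#'   `localization_deg`, `depth_fraction`, `depth_pct` and the injected truth
#'   columns.
#' @export
quantify_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rec <- purrr::map(cohort$studies, quantify_study, ...)
  dplyr::bind_cols(
    cohort$truth,
    purrr::map_dfr(rec, function(m) {
      tibble(extent_fraction = m$extent_fraction,
             extent_pct = 100 * m$extent_fraction,
             localization_deg = m$localization_deg,
             depth_fraction = m$depth_fraction,
             depth_pct = if (is.na(m$depth_fraction)) NA_real_
                         else 100 * m$depth_fraction)
    })
  )
}
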