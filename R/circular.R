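# Circular statistics on angles in degrees. Used for artifact localization
# (angle of the artifact centre on the short-axis ring) and for cohort
# summaries of localization, where linear means would break near the 0/360 wrap.

#' Circular mean of angles
#'
#' Mean resultant direction of a set of angles, optionally weighted. Angles are
#' degrees; the result is wrapped to `[0, 360)`.
#'
#' @param theta_deg Numeric vector of angles in degrees.
#' @param w Optional non-negative weights, recycled against `theta_deg`.
#' @return A single angle in degrees, or `NA` (with a warning) when the input
#'   is empty or the mean resultant vector has zero length (perfectly
#'   antipodal input), in which case no direction is defined.
#' @examples
#' circ_mean_deg(c(350, 10))   # 0, not 180
#' circ_mean_deg(c(105, 135, 165, 195))
#' @export
circ_mean_deg <- function(theta_deg, w = NULL) {
  if (length(theta_deg) == 0L) {
    warn("circular mean of an empty set is undefined")
    return(NA_real_)
  }
  w <- w %||% rep(1, length(theta_deg))
  stopifnot(length(w) == length(theta_deg), all(w >= 0))
  th <- theta_deg * pi / 180
  C <- sum(w * cos(th)) / sum(w)
  S <- sum(w * sin(th)) / sum(w)
  if (sqrt(C^2 + S^2) < 1e-10) {
    warn("zero resultant vector: circular mean undefined (antipodal angles)")
    return(NA_real_)
  }
  res <- (atan2(S, C) * 180 / pi) %% 360
  if (360 - res < 1e-9) res <- 0  # guard against 360-minus-epsilon wrap
  res
}

#' Circular standard deviation of angles
#'
#' `sqrt(-2 log R)` expressed in degrees, where `R` is the mean resultant
#' length. Zero for identical angles, infinite for a uniform spread.
#'
#' @inheritParams circ_mean_deg
#' @return Standard deviation in degrees (possibly `Inf`).
#' @export
circ_sd_deg <- function(theta_deg) {
  stopifnot(length(theta_deg) >= 1L)
  th <- theta_deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  if (R <= 0) return(Inf)
  sqrt(-2 * log(min(R, 1))) * 180 / pi
}

#' Signed shortest angular difference
#'
#' `a - b` on the circle, in `(-180, 180]` degrees. Used to difference
#' localization angles before a paired test so that 358 vs 2 counts as -4,
#' not 356.
#'
#' @param a,b Angles in degrees.
#' @return Signed differences in degrees.
#' @export
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
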