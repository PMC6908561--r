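# Cohort-level statistics: mean +/- SD summaries (circular for angles), the
# paired t test between cameras, and the summary table builder.

#' Mean and standard deviation of a metric
#'
#' Arithmetic mean and sample SD (n - 1 denominator); for angular metrics the
#' circular mean and circular SD are used instead, and the result is flagged.
#'
#' @param values Numeric vector (`NA`s dropped).
#' @param angular Treat values as angles in degrees.
#' @return A one-row tibble: `mean`, `sd` (`NA` when n < 2), `n`, `angular`.
#' @examples
#' mean_sd(c(1, 2, 3))
#' mean_sd(c(350, 10), angular = TRUE)
#' @export
mean_sd <- function(values, angular = FALSE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) return(tibble(mean = NA_real_, sd = NA_real_, n = 0L,
                             angular = angular))
  if (angular) {
    tibble(mean = circ_mean_deg(values),
           sd = if (n >= 2L) circ_sd_deg(values) else NA_real_,
           n = n, angular = TRUE)
  } else {
    tibble(mean = mean(values),
           sd = if (n >= 2L) sd(values) else NA_real_,
           n = n, angular = FALSE)
  }
}

#' Paired t test between two cameras
#'
#' Classical paired t test on aligned per-subject metric values:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p value from the t distribution. For angular metrics the
#' differences are taken on the circle (signed shortest angular difference),
#' avoiding wrap artifacts near 0/360.
#'
#' When all differences are zero the test is degenerate: `t = 0`, `p = 1`,
#' flagged. Constant non-zero differences (zero SD) are also flagged, with
#' `t = +/-Inf` and `p = 0`.
#'
#' @param a,b Aligned metric vectors for cameras A and B (pairs with any `NA`
#'   are dropped).
#' @param angular Difference the values on the circle.
#' @return An object of class `paired_t_test`: list with `statistic`,
#'   `parameter` (df), `p.value`, `estimate` (mean difference), `n`,
#'   `degenerate`, `angular`, `method`.
#' @examples
#' pt <- paired_t(c(23, 25, 21, 24, 26), c(15, 16, 14, 18, 15))
#' tidy(pt)
#' @export
paired_t <- function(a, b, angular = FALSE) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) abort("paired t test needs at least 2 complete pairs")
  d <- if (angular) ang_diff_deg(a, b) else a - b
  md <- mean(d)
  sdd <- sd(d)
  # zero-variance differences, allowing for floating-point noise on constants
  degenerate <- sdd == 0 || sdd < 1e-9 * abs(md)
  if (degenerate) {
    stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    warn("all paired differences are equal: degenerate paired t test")
  } else {
    stat <- md / (sdd / sqrt(n))
    p <- 2 * pt(-abs(stat), df = n - 1)
  }
  structure(
    list(statistic = stat, parameter = n - 1L, p.value = p, estimate = md,
         n = n, degenerate = degenerate, angular = angular,
         method = "Paired t test"),
    class = "paired_t_test"
  )
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf("%s%s: t = %.4g, df = %d, p = %.4g (mean difference %.4g, n = %d)%s\n",
              x$method, if (x$angular) " (circular differences)" else "",
              x$statistic, x$parameter, x$p.value, x$estimate, x$n,
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' Tidy a paired t test
#'
#' @param x A `paired_t_test`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `statistic`, `p.value`, `parameter`,
#'   `n`, `degenerate`, `method`.
#' @method tidy paired_t_test
#' @export
tidy.paired_t_test <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, p.value = x$p.value,
         parameter = x$parameter, n = x$n, degenerate = x$degenerate,
         method = x$method)
}

#' Summarize per-acquisition metrics by camera
#'
#' Builds the per-camera mean +/- SD table of extent, depth and localization,
#' plus paired t tests across cameras for each metric when paired acquisitions
#' exist. Localization is summarized with circular statistics and differenced
#' on the circle before testing.
#'
#' @param metrics A data frame with one row per (acquisition, camera):
#'   columns `acquisition` (subject/acquisition id), `camera`, and the metric
#'   columns `extent_pct`, `depth_pct`, `localization_deg` (any subset).
#' @return An object of class `cohort_summary`: list with `summary` (tibble:
#'   camera, metric, mean, sd, n, angular) and `tests` (tibble of paired t
#'   results per metric; `NULL` unless exactly two cameras with complete
#'   pairs).
#' @export
summarize_cohort <- function(metrics) {
  metrics <- as_tibble(metrics)
  stopifnot(all(c("acquisition", "camera") %in% names(metrics)))
  metric_cols <- intersect(c("extent_pct", "depth_pct", "localization_deg"),
                           names(metrics))
  if (length(metric_cols) == 0L) abort("no metric columns found")
  is_ang <- function(m) m == "localization_deg"

  summary <- purrr::map_dfr(metric_cols, function(m) {
    metrics |>
      dplyr::group_by(.data$camera) |>
      dplyr::group_modify(~ mean_sd(.x[[m]], angular = is_ang(m))) |>
      dplyr::ungroup() |>
      dplyr::mutate(metric = m, .after = "camera")
  })

  cams <- unique(metrics$camera)
  tests <- NULL
  if (length(cams) == 2L) {
    wide <- lapply(metric_cols, function(m) {
      w <- tidyr::pivot_wider(metrics[, c("acquisition", "camera", m)],
                              names_from = "camera",
                              values_from = dplyr::all_of(m))
      w <- w[stats::complete.cases(w), ]
      if (nrow(w) < 2L) return(NULL)
      res <- paired_t(w[[cams[1]]], w[[cams[2]]], angular = is_ang(m))
      dplyr::mutate(tidy(res), metric = m, camera_a = cams[1],
                    camera_b = cams[2], .before = 1)
    })
    wide <- wide[!vapply(wide, is.null, logical(1))]
    if (length(wide)) tests <- dplyr::bind_rows(wide)
  }
  structure(list(summary = summary, tests = tests),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$summary)
  if (!is.null(x$tests)) {
    cat("paired camera comparisons:\n")
    print(x$tests)
  }
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) x$summary

#' @rdname summarize_cohort
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  if (is.null(x$tests)) tibble() else x$tests
}
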