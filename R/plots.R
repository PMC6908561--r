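# Polar ("bullseye") maps of sector grids, ratio maps and artifact masks:
# apex at the centre, base at the periphery, anterior (0 degrees) at the top,
# angles increasing clockwise through lateral, inferior and septal.

bullseye_base <- function(df, fill) {
  n_slices <- max(df$slice)
  df$ring <- n_slices - df$slice + 1  # basal slice on the outermost ring
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sector_center_deg, y = .data$ring, fill = {{ fill }})) +
    ggplot2::geom_tile(width = 30, height = 1, colour = "grey85",
                       linewidth = 0.1) +
    ggplot2::coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270),
                                labels = c("anterior", "lateral",
                                           "inferior", "septal")) +
    ggplot2::scale_y_continuous(limits = c(-1, n_slices + 0.5)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Polar map of a sector grid
#'
#' @param object A `sector_grid` from [sectorize()].
#' @param ... Unused.
#' @return A ggplot bullseye plot of the normalized segment counts.
#' @method autoplot sector_grid
#' @export
autoplot.sector_grid <- function(object, ...) {
  bullseye_base(object, .data$value) +
    ggplot2::scale_fill_viridis_c(name = "normalized\ncounts")
}

#' Polar map of a NAC/AC ratio map
#'
#' Undefined segments (zero AC counts) are shown in grey.
#'
#' @param object A `ratio_map` from [compute_ratio()].
#' @param ... Unused.
#' @return A ggplot bullseye plot of per-segment NAC/AC ratios.
#' @method autoplot ratio_map
#' @export
autoplot.ratio_map <- function(object, ...) {
  bullseye_base(object, .data$ratio) +
    ggplot2::scale_fill_gradient2(name = "NAC/AC", midpoint = 1,
                                  low = "#b2182b", mid = "white",
                                  high = "#2166ac", na.value = "grey70")
}

#' Polar map of a delineated artifact mask
#'
#' Ratio map with the delineated artifact segments outlined.
#'
#' @param object An `artifact_mask` from [delineate()].
#' @param ... Unused.
#' @return A ggplot bullseye plot.
#' @method autoplot artifact_mask
#' @export
autoplot.artifact_mask <- function(object, ...) {
  p <- autoplot.ratio_map(object, ...)
  hit <- object[object$artifact, , drop = FALSE]
  if (nrow(hit) > 0) {
    hit$ring <- max(object$slice) - hit$slice + 1
    p <- p + ggplot2::geom_tile(
      data = hit,
      ggplot2::aes(x = .data$sector_center_deg, y = .data$ring),
      width = 30, height = 1, fill = NA, colour = "black", linewidth = 0.5)
  }
  p + ggplot2::labs(
    subtitle = sprintf("threshold %.2f: %d artifact segment(s)",
                       attr(object, "threshold_used") %||% NA,
                       sum(object$artifact)))
}

#' Bullseye plot of any per-segment quantity
#'
#' Convenience wrapper: plots a column of a per-segment tibble as a polar map.
#'
#' @param df Data frame with `slice`, `sector_center_deg` and the column.
#' @param column Column to map to fill (tidy-eval).
#' @return A ggplot object.
#' @export
plot_bullseye <- function(df, column) {
  bullseye_base(as_tibble(df), {{ column }}) +
    ggplot2::scale_fill_viridis_c()
}
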