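#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_col
#'   geom_histogram labs facet_wrap scale_y_continuous theme_minimal
#'   after_stat position_identity
NULL

#' @export
ggplot2::autoplot

#' Plot an absorption spectrum
#'
#' Total, parallel and perpendicular channels (and optionally per-wall
#' contributions) against energy or wavelength.
#'
#' @param object An `absorption_spectrum`.
#' @param x_axis `"energy"` (cm^-1) or `"wavelength"` (nm; simple
#'   reindexing, no Jacobian).
#' @param walls Include per-wall channels.
#' @param normalize Scale the total-channel maximum to 1.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.absorption_spectrum <- function(object, x_axis = c("energy", "wavelength"),
                                         walls = TRUE, normalize = TRUE, ...) {
  x_axis <- match.arg(x_axis)
  df <- as_tibble(object)
  chans <- c("total", "parallel", "perpendicular")
  if (walls) chans <- c(chans, intersect(c("IW", "OW"), names(df)))
  sc <- if (normalize && max(df$total) > 0) max(df$total) else 1
  long <- tidyr::pivot_longer(df[c(x_axis, chans)], -1,
                              names_to = "channel", values_to = "intensity")
  long$intensity <- long$intensity / sc
  ggplot(long, aes(x = .data[[x_axis]], y = .data$intensity,
                   colour = .data$channel)) +
    geom_line() +
    labs(x = if (x_axis == "energy") "Energy (cm⁻¹)" else "Wavelength (nm)",
         y = if (normalize) "Absorption (norm.)" else "Absorption",
         colour = NULL) +
    theme_minimal()
}

#' Plot a pair angle-distance map
#'
#' @param object A `pair_map` from [pair_angle_distance_map()].
#' @param ... Unused.
#' @return A ggplot (tiles of normalized pair density, faceted by wall).
#' @export
autoplot.pair_map <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$r, y = .data$phi,
                                fill = .data$density)) +
    geom_tile(width = attr(object, "dr"), height = attr(object, "dphi")) +
    facet_wrap(~wall) +
    labs(x = expression(r[ij] ~ "(nm)"), y = expression(phi[ij] ~ "(deg)"),
         fill = "pair density") +
    theme_minimal()
}

#' Plot a tube structure (axial projection)
#'
#' @param object A `tube_structure`.
#' @param ... Unused.
#' @return A ggplot of site positions in the xy plane, coloured by wall.
#' @export
autoplot.tube_structure <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y,
                                colour = .data$wall)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    labs(x = "x (nm)", y = "y (nm)", colour = NULL) +
    theme_minimal()
}

#' Plot per-wall coupling-sum histograms
#'
#' Overlays the ideal and disordered distributions of the per-site coupling
#' sum produced by [coupling_sum_histogram()].
#'
#' @param result The list returned by [coupling_sum_histogram()].
#' @param binwidth Histogram bin width, cm^-1.
#' @return A ggplot.
#' @export
plot_coupling_sums <- function(result, binwidth = 50) {
  ggplot(result$values, aes(x = .data$coupling_sum, fill = .data$kind)) +
    geom_histogram(aes(y = after_stat(.data$density)), binwidth = binwidth,
                   alpha = 0.6, position = position_identity()) +
    facet_wrap(~wall) +
    labs(x = expression(sum(J[ij], j != i) ~ "(cm"^-1 * ")"),
         y = "density", fill = NULL) +
    theme_minimal()
}
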