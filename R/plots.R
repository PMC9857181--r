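# ggplot2 visualizations: rank maps and density profiles of the interface
# zone, Kaplan-Meier curves, and risk-tier survival.

# hexagon side from the axial/center relationship cx = x0 + 1.5 * s * q
infer_side_um <- function(hexes) {
  i <- which(hexes$q != hexes$q[1])[1]
  if (is.na(i)) {
    j <- which(hexes$r != hexes$r[1])[1]
    if (is.na(j)) abort("cannot infer hexagon side from a single hexagon")
    return((hexes$cy_um[j] - hexes$cy_um[1]) / (sqrt(3) * (hexes$r[j] - hexes$r[1])))
  }
  (hexes$cx_um[i] - hexes$cx_um[1]) / (1.5 * (hexes$q[i] - hexes$q[1]))
}

hex_polygons <- function(hexes, fill) {
  s <- infer_side_um(hexes)
  ang <- (0:5) * pi / 3
  n <- nrow(hexes)
  tibble(
    id = rep(seq_len(n), each = 6L),
    x = rep(hexes$cx_um, each = 6L) + s * rep(cos(ang), n),
    y = rep(hexes$cy_um, each = 6L) + s * rep(sin(ang), n),
    fill = rep(fill, each = 6L)
  )
}

#' Rank map of a region's hexagonal grid
#'
#' Draws each hexagon colored by its signed interface rank; the rank-0 edge
#' sits between the positive (epithelial) and negative (stromal) aspects.
#'
#' @param ranked A ranked hexagon tibble (see [assign_ranks()]).
#' @param max_rank Clamp color scale at this absolute rank (default 4).
#' @return A ggplot object.
#' @export
plot_rank_map <- function(ranked, max_rank = 4) {
  stopifnot(all(c("rank", "cx_um", "cy_um") %in% names(ranked)))
  rk <- pmin(pmax(ranked$rank, -max_rank), max_rank)
  poly <- hex_polygons(ranked, fill = rk)
  ggplot(poly, aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$fill)) +
    geom_polygon(color = "grey30", linewidth = 0.1) +
    scale_fill_gradient2(low = "#1b7837", mid = "#ffffbf", high = "#c51b7d",
                         midpoint = 0, name = "rank", na.value = "grey85") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}

#' @rdname plot_rank_map
#' @param object An `interface_zone` tibble.
#' @param ... Unused.
#' @method autoplot interface_zone
#' @export
autoplot.interface_zone <- function(object, ...) {
  poly <- hex_polygons(object, fill = object$compartment)
  ggplot(poly, aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$fill)) +
    geom_polygon(color = "grey30", linewidth = 0.1) +
    scale_fill_manual(values = c(S = "#1b7837", TE = "#ffd92f", T = "#c51b7d"),
                      name = "compartment") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}

#' Per-rank density profile of the interface zone
#'
#' Boxplots of the per-hexagon marker density by signed rank — the density
#' gradient across the epithelium-stroma interface.
#'
#' @param ranked A ranked hexagon tibble with `cd8_density_mm2`.
#' @param max_rank Restrict to ranks within this absolute value (default 5).
#' @return A ggplot object.
#' @export
plot_density_profile <- function(ranked, max_rank = 5) {
  d <- ranked |>
    filter(!is.na(.data$rank), abs(.data$rank) <= max_rank,
           !is.na(.data$cd8_density_mm2))
  ggplot(d, aes(x = factor(.data$rank), y = .data$cd8_density_mm2)) +
    geom_boxplot(fill = "grey90", outlier.size = 0.6) +
    labs(x = "interface rank (negative = stroma, positive = epithelium)",
         y = "CD8+ density (cells/mm²)") +
    theme_minimal()
}

#' @rdname kaplan_meier
#' @param object A `km_curve` tibble.
#' @param ... Unused.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  has_groups <- !all(is.na(object$group))
  p <- ggplot(object, aes(x = .data$time, y = .data$survival))
  if (has_groups) {
    p <- p + geom_step(aes(color = .data$group), linewidth = 0.7)
  } else {
    p <- p + geom_step(linewidth = 0.7)
  }
  p +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (months)", y = "survival probability") +
    theme_minimal()
}

#' @rdname stratified_survival
#' @param object A `risk_strata` object.
#' @method autoplot risk_strata
#' @export
autoplot.risk_strata <- function(object, ...) {
  autoplot(object$km) +
    scale_color_manual(values = c(low = "#1a9850", intermediate = "#fdae61",
                                  high = "#d73027"),
                       name = "risk") +
    labs(title = "Survival by combined prognostic score tier")
}
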