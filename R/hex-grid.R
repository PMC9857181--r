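# Hexagonal grid tiling and per-hexagon aggregation.
#
# Convention (fixed, documented): flat-top hexagons in axial (q, r) coordinates.
# The center of hexagon (q, r) sits at
#   x = 1.5 * side * q
#   y = sqrt(3) * side * (r + q / 2)
# relative to the grid origin (top-left of the tiled extent, y increasing
# downward, image convention). A hexagon with side s has area (3*sqrt(3)/2)*s^2.

HEX_DIRECTIONS <- matrix(
  c(1L, 0L, 1L, -1L, 0L, -1L, -1L, 0L, -1L, 1L, 0L, 1L),
  ncol = 2, byrow = TRUE, dimnames = list(NULL, c("dq", "dr"))
)

hex_key <- function(q, r) q * 1e5 + r

#' Build a hexagonal grid covering a rectangular extent
#'
#' Tiles the rectangle `[0, width] x [0, height]` (in micrometers, relative to
#' `origin_um`) with flat-top hexagons of the given side length. Hexagons whose
#' center falls within one side length of the rectangle are included, so every
#' point of the extent is covered by some grid hexagon.
#'
#' @param extent_um Numeric length-2, physical width and height in micrometers.
#' @param side_um Hexagon side length in micrometers. The default of 65 gives
#'   a hexagon area of (3*sqrt(3)/2)*65^2 = 10976.9 um^2.
#' @param origin_um Numeric length-2, physical position of the grid origin
#'   (top-left corner) in slide coordinates.
#'
#' @return An object of class `hex_grid`: a list with elements `side_um`,
#'   `origin_um`, `extent_um` and `hexes`, a tibble with one row per hexagon
#'   (`q`, `r`, `cx_um`, `cy_um`; centers in slide coordinates).
#' @export
#' @examples
#' grid <- build_hex_grid(c(1000, 1000), side_um = 65)
#' hex_area_um2(65)
build_hex_grid <- function(extent_um, side_um = 65, origin_um = c(0, 0)) {
  if (length(extent_um) != 2 || any(!is.finite(extent_um)) || any(extent_um <= 0)) {
    abort("`extent_um` must be two positive finite numbers (width, height).")
  }
  if (!is.numeric(side_um) || length(side_um) != 1 || !is.finite(side_um) || side_um <= 0) {
    abort("`side_um` must be a single positive number.")
  }
  w <- extent_um[[1]]
  h <- extent_um[[2]]
  s <- side_um
  q_seq <- seq(floor(-s / (1.5 * s)), ceiling((w + s) / (1.5 * s)))
  hexes <- purrr::map(q_seq, function(q) {
    cx <- 1.5 * s * q
    if (cx < -s || cx > w + s) return(NULL)
    r_lo <- ceiling(-s / (sqrt(3) * s) - q / 2)
    r_hi <- floor((h + s) / (sqrt(3) * s) - q / 2)
    if (r_hi < r_lo) return(NULL)
    r <- seq(r_lo, r_hi)
    tibble(q = as.integer(q), r = as.integer(r),
           cx_um = cx, cy_um = sqrt(3) * s * (r + q / 2))
  }) |> list_rbind()
  hexes <- hexes |>
    mutate(cx_um = .data$cx_um + origin_um[[1]],
           cy_um = .data$cy_um + origin_um[[2]]) |>
    arrange(.data$q, .data$r)
  structure(
    list(side_um = s, origin_um = as.numeric(origin_um),
         extent_um = as.numeric(extent_um), hexes = hexes),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> side %.4g um, extent %.4g x %.4g um, %d hexagons\n",
              x$side_um, x$extent_um[[1]], x$extent_um[[2]], nrow(x$hexes)))
  invisible(x)
}

#' Hexagon area for a given side length
#'
#' @param side_um Hexagon side length in micrometers.
#' @return Area in square micrometers, `(3 * sqrt(3) / 2) * side_um^2`.
#' @export
hex_area_um2 <- function(side_um) {
  (3 * sqrt(3) / 2) * side_um^2
}

# Fractional axial coordinates -> nearest hexagon via cube rounding.
# Deterministic; for points equidistant to two centers the cube-rounding
# result is tie-broken toward the lexicographically smaller (q, r).
axial_round <- function(qf, rf) {
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  xr <- round(xf)
  yr <- round(yf)
  zr <- round(zf)
  dx <- abs(xr - xf)
  dy <- abs(yr - yf)
  dz <- abs(zr - zf)
  fix_x <- dx >= dy & dx >= dz
  fix_z <- !fix_x & dz > dy
  xr[fix_x] <- -yr[fix_x] - zr[fix_x]
  zr[fix_z] <- -xr[fix_z] - yr[fix_z]
  list(q = as.integer(xr), r = as.integer(zr))
}

#' Map points to their containing hexagon
#'
#' Assigns each point to the grid hexagon whose center is nearest (standard
#' axial cube rounding, equivalent to point-in-hexagon containment). Points
#' falling outside the tiled grid are still assigned an axial index but are
#' flagged `external`.
#'
#' @param grid A `hex_grid`.
#' @param x_um,y_um Point coordinates in micrometers (slide coordinates).
#' @return A tibble with columns `q`, `r`, `external`.
#' @export
point_to_hex <- function(grid, x_um, y_um) {
  stopifnot(inherits(grid, "hex_grid"))
  s <- grid$side_um
  px <- x_um - grid$origin_um[[1]]
  py <- y_um - grid$origin_um[[2]]
  qf <- (2 / 3) * px / s
  rf <- (-px / 3 + sqrt(3) / 3 * py) / s
  ax <- axial_round(qf, rf)
  known <- hex_key(grid$hexes$q, grid$hexes$r)
  tibble(q = ax$q, r = ax$r,
         external = !(hex_key(ax$q, ax$r) %in% known))
}

#' Axial neighbors of hexagons
#'
#' @param q,r Integer axial coordinates (vectors of equal length).
#' @return A tibble with columns `q`, `r` (the source hexagon) and
#'   `nq`, `nr` (each of its six neighbors), six rows per input hexagon.
#' @export
hex_neighbors <- function(q, r) {
  n <- length(q)
  q6 <- rep(as.integer(q), each = 6L)
  r6 <- rep(as.integer(r), each = 6L)
  tibble(
    q = q6,
    r = r6,
    nq = q6 + rep(HEX_DIRECTIONS[, "dq"], n),
    nr = r6 + rep(HEX_DIRECTIONS[, "dr"], n)
  )
}

#' Hex-graph distance between axial coordinates
#'
#' @param q1,r1,q2,r2 Axial coordinates.
#' @return Integer graph distance on the hexagonal lattice.
#' @export
hex_distance <- function(q1, r1, q2, r2) {
  dq <- q1 - q2
  dr <- r1 - r2
  as.integer((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
}

# Vertices of flat-top hexagons, for plotting. Returns a tibble with 6 rows
# per hexagon: q, r, vx_um, vy_um, vertex.
hex_vertices <- function(grid, q, r) {
  s <- grid$side_um
  cx <- grid$origin_um[[1]] + 1.5 * s * q
  cy <- grid$origin_um[[2]] + sqrt(3) * s * (r + q / 2)
  ang <- (0:5) * pi / 3
  tibble(
    q = rep(as.integer(q), each = 6L),
    r = rep(as.integer(r), each = 6L),
    vertex = rep(1:6, length(q)),
    vx_um = rep(cx, each = 6L) + s * rep(cos(ang), length(q)),
    vy_um = rep(cy, each = 6L) + s * rep(sin(ang), length(q))
  )
}

#' Aggregate cells and tissue-class areas on a hexagonal grid
#'
#' For each grid hexagon whose center lies inside the annotated region, counts
#' the marker-positive cells assigned to it and measures the area of each
#' tissue class (epithelium, stroma, background) from the label raster.
#' Per-hexagon marker density is the positive-cell count divided by the tissue
#' area (epithelium + stroma) in the hexagon, in cells/mm^2; hexagons whose
#' tissue area is below `min_tissue_fraction` of the full hexagon area carry
#' `NA` density and are excluded from downstream density profiles.
#'
#' @param cells A tibble of cell records with columns `x_um`, `y_um`,
#'   `cd8_positive` (logical or 0/1).
#' @param tissue A [tissue_map()].
#' @param annotation A region annotation tibble (see [region_annotation()]).
#' @param grid A `hex_grid`; defaults to a grid over the annotation bounding
#'   box with 65 um side length.
#' @param region_label Which annotation label to aggregate
#'   (`"malignant"` or `"non_malignant"`); defaults to the only label present.
#' @param min_tissue_fraction Minimum tissue area as a fraction of hexagon
#'   area for the hexagon to receive a density value (default 0.1).
#'
#' @return A tibble of class `hex_aggregate` with one row per retained
#'   hexagon: `q`, `r`, `cx_um`, `cy_um`, `cd8_count`, `area_epithelium_um2`,
#'   `area_stroma_um2`, `area_background_um2`, `tissue_fraction`,
#'   `cd8_density_mm2`, `region_label`. The attribute `grid` carries the grid.
#' @export
hex_aggregate <- function(cells, tissue, annotation, grid = NULL,
                          region_label = NULL, min_tissue_fraction = 0.1) {
  stopifnot(inherits(tissue, "tissue_map"))
  annotation <- validate_annotation(annotation)
  labels_present <- unique(annotation$label)
  if (is.null(region_label)) {
    if (length(labels_present) != 1) {
      abort("`region_label` must be given when the annotation has several labels.")
    }
    region_label <- labels_present
  }
  rings <- annotation$ring[annotation$label == region_label]
  if (length(rings) == 0) {
    abort(sprintf("annotation has no polygons labeled '%s'", region_label))
  }
  if (is.null(grid)) {
    allxy <- do.call(rbind, rings)
    bb_min <- apply(allxy, 2, min)
    bb_max <- apply(allxy, 2, max)
    grid <- build_hex_grid(bb_max - bb_min, side_um = 65, origin_um = bb_min)
  }

  # retained hexagons: center inside the region polygon(s)
  bnd <- do.call(rbind, lapply(rings, function(rg) rbind(rg, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  inside <- mgcv::in.out(bnd, as.matrix(grid$hexes[, c("cx_um", "cy_um")]))
  kept <- grid$hexes[inside, , drop = FALSE]
  if (nrow(kept) == 0) abort("no hexagons in region")

  areas <- pixel_class_areas(grid, tissue)
  key_kept <- hex_key(kept$q, kept$r)

  out <- kept |>
    mutate(key = key_kept) |>
    left_join(areas, by = "key") |>
    mutate(across(c("area_epithelium_um2", "area_stroma_um2", "area_background_um2"),
                  ~ tidyr::replace_na(.x, 0)))

  # cell counts per hexagon
  cells <- validate_cells(cells)
  if (nrow(cells) > 0) {
    pos <- cells[as.logical(cells$cd8_positive), , drop = FALSE]
    if (nrow(pos) > 0) {
      hx <- point_to_hex(grid, pos$x_um, pos$y_um)
      counts <- tibble(key = hex_key(hx$q, hx$r)) |>
        count(.data$key, name = "cd8_count")
      out <- out |>
        left_join(counts, by = "key") |>
        mutate(cd8_count = tidyr::replace_na(.data$cd8_count, 0L))
    } else {
      out$cd8_count <- 0L
    }
  } else {
    out$cd8_count <- 0L
  }

  hex_area <- hex_area_um2(grid$side_um)
  out <- out |>
    mutate(
      tissue_area_um2 = .data$area_epithelium_um2 + .data$area_stroma_um2,
      tissue_fraction = .data$tissue_area_um2 / hex_area,
      cd8_density_mm2 = ifelse(
        .data$tissue_fraction >= min_tissue_fraction,
        .data$cd8_count / (.data$tissue_area_um2 / 1e6),
        NA_real_
      ),
      region_label = region_label
    ) |>
    select("q", "r", "cx_um", "cy_um", "cd8_count",
           "area_epithelium_um2", "area_stroma_um2", "area_background_um2",
           "tissue_area_um2", "tissue_fraction", "cd8_density_mm2",
           "region_label")
  attr(out, "grid") <- grid
  attr(out, "min_tissue_fraction") <- min_tissue_fraction
  class(out) <- c("hex_aggregate", class(out))
  out
}

# Tabulate per-hexagon tissue-class areas from the label raster, processing
# the raster in row chunks to bound memory. Pixel centers are taken at
# (col - 0.5, row - 0.5) * pixel_size relative to the raster origin.
pixel_class_areas <- function(grid, tissue, chunk_rows = 512L) {
  lab <- tissue$labels
  px <- tissue$pixel_size_um
  nr <- nrow(lab)
  nc <- ncol(lab)
  xs <- tissue$origin_um[[1]] + (seq_len(nc) - 0.5) * px
  acc <- list()
  i <- 1L
  row0 <- 1L
  while (row0 <= nr) {
    row1 <- min(row0 + chunk_rows - 1L, nr)
    rows <- row0:row1
    ys <- tissue$origin_um[[2]] + (rows - 0.5) * px
    chunk <- lab[rows, , drop = FALSE]
    xm <- rep(xs, each = length(rows))
    ym <- rep(ys, times = nc)
    hx <- point_to_hex(grid, xm, ym)
    key <- hex_key(hx$q, hx$r)
    lv <- as.integer(chunk)
    tab <- rowsum(cbind(epi = as.numeric(lv == 1L),
                        str = as.numeric(lv == 2L),
                        bg = as.numeric(lv == 0L)),
                  group = key)
    acc[[i]] <- tibble(key = as.numeric(rownames(tab)),
                       epi = tab[, "epi"], str = tab[, "str"], bg = tab[, "bg"])
    i <- i + 1L
    row0 <- row1 + 1L
  }
  px2 <- px * px
  list_rbind(acc) |>
    group_by(.data$key) |>
    summarise(across(c("epi", "str", "bg"), sum), .groups = "drop") |>
    transmute(key = .data$key,
              area_epithelium_um2 = .data$epi * px2,
              area_stroma_um2 = .data$str * px2,
              area_background_um2 = .data$bg * px2)
}
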