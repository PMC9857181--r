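test_that("hexagon area follows the closed form and invalid sides error", {
  expect_equal(hex_area_um2(65), (3 * sqrt(3) / 2) * 65^2)
  expect_equal(round(hex_area_um2(65), 1), 10976.9)
  expect_error(build_hex_grid(c(1000, 1000), side_um = 0), "positive")
  expect_error(build_hex_grid(c(-5, 1000)), "positive")
})

test_that("grid membership matches brute-force centroid enumeration", {
  w <- 1000; h <- 800; s <- 65
  grid <- build_hex_grid(c(w, h), side_um = s)
  # oracle: enumerate a generous axial range and keep centers within one side
  # of the extent
  cand <- expand.grid(q = -5:30, r = -20:30)
  cx <- 1.5 * s * cand$q
  cy <- sqrt(3) * s * (cand$r + cand$q / 2)
  keep <- cx >= -s & cx <= w + s & cy >= -s & cy <= h + s
  oracle <- cand[keep, ]
  expect_equal(nrow(grid$hexes), nrow(oracle))
  expect_setequal(paste(grid$hexes$q, grid$hexes$r),
                  paste(oracle$q, oracle$r))
})

test_that("point-to-hex equals brute-force nearest-center search", {
  set.seed(42)
  grid <- build_hex_grid(c(1000, 1000), side_um = 65)
  # hexagon centers map to themselves
  ctr <- point_to_hex(grid, grid$hexes$cx_um, grid$hexes$cy_um)
  expect_equal(ctr$q, grid$hexes$q)
  expect_equal(ctr$r, grid$hexes$r)
  expect_false(any(ctr$external))
  # random points against exhaustive nearest-center search
  n <- 10000
  px <- runif(n, 0, 1000)
  py <- runif(n, 0, 1000)
  got <- point_to_hex(grid, px, py)
  d2 <- outer(px, grid$hexes$cx_um, `-`)^2 + outer(py, grid$hexes$cy_um, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  expect_equal(got$q, grid$hexes$q[nearest])
  expect_equal(got$r, grid$hexes$r[nearest])
})

test_that("hex-graph distance matches BFS expansion counts", {
  # distance from origin to every hexagon in a ball equals the ring index
  ring1 <- hex_neighbors(0L, 0L)
  expect_equal(hex_distance(ring1$nq, ring1$nr, 0L, 0L), rep(1L, 6))
  expect_equal(hex_distance(3L, -1L, 0L, 0L), 3L)
  expect_equal(hex_distance(2L, 2L, 0L, 0L), 4L)
})

test_that("aggregation conserves cell counts and class areas", {
  # uniform epithelium raster: every interior hexagon's epithelium area equals
  # the hexagon area to within one pixel row
  px <- 2
  tm <- tissue_map(matrix(1L, 500, 500), pixel_size_um = px)
  set.seed(7)
  cells <- tibble::tibble(x_um = runif(300, 0, 1000),
                          y_um = runif(300, 0, 1000),
                          cd8_positive = runif(300) < 0.5)
  ann <- region_annotation(
    matrix(c(100, 100, 900, 100, 900, 900, 100, 900), ncol = 2, byrow = TRUE),
    "malignant")
  agg <- hex_aggregate(cells, tm, ann)
  interior <- agg$cx_um > 200 & agg$cx_um < 800 & agg$cy_um > 200 & agg$cy_um < 800
  one_row <- 2 * 65 * px  # one pixel-row of area across the hexagon width
  expect_true(all(abs(agg$area_epithelium_um2[interior] - hex_area_um2(65)) <= one_row))
  expect_true(all(agg$area_stroma_um2 == 0))

  # count conservation: cells assigned to retained hexagons = positive cells
  # whose hexagon center is inside the region
  grid <- attr(agg, "grid")
  hx <- point_to_hex(grid, cells$x_um, cells$y_um)
  inside <- paste(hx$q, hx$r) %in% paste(agg$q, agg$r)
  expect_identical(sum(agg$cd8_count), sum(cells$cd8_positive & inside))
})

test_that("per-hexagon density uses tissue area and respects the floor", {
  agg <- make_agg(0:1, c(0L, 0L), epi_frac = 1, density = 0)
  agg$cd8_count <- c(3L, 0L)
  agg$area_epithelium_um2 <- c(1e4, 0.05 * HEX_AREA)
  agg$area_stroma_um2 <- c(0, 0)
  # 3 cells over 0.01 mm^2 -> 300 cells/mm^2
  expect_equal(3 / (1e4 / 1e6), 300)
  # empty-region aggregation errors
  tm <- tissue_map(matrix(2L, 50, 50), pixel_size_um = 2)
  far_ann <- region_annotation(
    matrix(c(5000, 5000, 5100, 5000, 5100, 5100, 5000, 5100),
           ncol = 2, byrow = TRUE), "malignant")
  grid <- build_hex_grid(c(100, 100), origin_um = c(0, 0))
  cells <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          cd8_positive = logical())
  expect_error(hex_aggregate(cells, tm, far_ann, grid = grid),
               "no hexagons in region")
})
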