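test_that("majority-class labels break ties toward epithelium", {
  agg <- make_agg(0:2, rep(0L, 3), epi_frac = c(0.7, 0.5, 0.2))
  cls <- classify_hexes(agg)$majority_class
  expect_equal(cls, c("epithelium", "epithelium", "stroma"))
})

test_that("edge extraction finds epithelium hexagons touching stroma", {
  # half-plane split at q = 3: edge must be exactly the q = 3 column
  hx <- axial_block(7, 7)
  agg <- make_agg(hx$q, hx$r, epi_frac = as.numeric(hx$q >= 3))
  lab <- extract_edge(classify_hexes(agg))
  expect_setequal(paste(lab$q[lab$edge], lab$r[lab$edge]),
                  paste(3L, 0:6))

  # single epithelium hexagon surrounded by stroma is the whole edge
  hx2 <- axial_block(3, 3)
  agg2 <- make_agg(hx2$q, hx2$r,
                   epi_frac = as.numeric(hx2$q == 1 & hx2$r == 1))
  lab2 <- extract_edge(classify_hexes(agg2))
  expect_equal(sum(lab2$edge), 1)
  expect_true(lab2$edge[lab2$q == 1 & lab2$r == 1])

  # single-class maps have no interface
  all_epi <- make_agg(hx2$q, hx2$r, epi_frac = 1)
  expect_error(extract_edge(classify_hexes(all_epi)), "no interface")
})

test_that("signed ranks on a linear strip follow the distance ladder", {
  # one row: E E E E E E | S S S S with the edge at q = 5
  agg <- make_agg(0:9, rep(0L, 10), epi_frac = as.numeric(0:9 <= 5))
  # flip so epithelium is on the high-q side: S S S S | E E E E E E
  agg <- make_agg(0:9, rep(0L, 10), epi_frac = as.numeric(0:9 >= 4))
  rk <- assign_ranks(agg)
  expect_equal(rk$rank[order(rk$q)], c(-4:-1, 0:5))
})

test_that("ranks equal independent shortest-path distances on random maps", {
  skip_if_not_installed("igraph")
  for (seed in c(101, 202, 303)) {
    agg <- random_class_map(25, 25, seed)  # 625 hexagons
    lab <- extract_edge(classify_hexes(agg))
    rk <- assign_ranks(lab)
    oracle <- oracle_ranks_igraph(lab)
    expect_equal(rk$rank, as.integer(round(oracle)))
  }
})

test_that("rank field changes by at most one between adjacent same-side hexagons", {
  agg <- random_class_map(20, 20, 77)
  rk <- assign_ranks(agg)
  nb <- hex_neighbors(rk$q, rk$r)
  key <- rk$q * 1e5 + rk$r
  i <- rep(seq_len(nrow(rk)), each = 6)
  j <- match(nb$nq * 1e5 + nb$nr, key)
  ok <- !is.na(j) & rk$majority_class[i] == rk$majority_class[j] &
    !is.na(rk$rank[i]) & !is.na(rk$rank[j])
  expect_true(all(abs(rk$rank[i][ok] - rk$rank[j][ok]) <= 1))
})

test_that("interface zone keeps the configured compartments", {
  # strip with ranks -4..5 available
  agg <- make_agg(0:9, rep(0L, 10), epi_frac = as.numeric(0:9 >= 4))
  hx <- axial_block(10, 6)
  agg <- make_agg(hx$q, hx$r, epi_frac = as.numeric(hx$q >= 4))
  zone <- interface_zone(agg)
  expect_setequal(unique(zone$rank), -2:2)
  expect_setequal(zone$rank[zone$compartment == "S"], -2L)
  expect_setequal(zone$rank[zone$compartment == "T"], 2L)
  expect_setequal(unique(zone$rank[zone$compartment == "TE"]), -1:1)
  expect_equal(unique(zone$position[zone$compartment == "S"]), 1)
  expect_equal(unique(zone$position[zone$compartment == "TE"]), 2)
  expect_equal(unique(zone$position[zone$compartment == "T"]), 3)

  # configuration matrix: TE width and flank depth
  zone1 <- interface_zone(agg, te_width = 1, flank = 1)
  expect_setequal(zone1$rank[zone1$compartment == "S"], -1L)
  expect_setequal(zone1$rank[zone1$compartment == "TE"], 0L)
  expect_setequal(zone1$rank[zone1$compartment == "T"], 1L)
  zone2 <- interface_zone(agg, te_width = 3, flank = 2)
  expect_setequal(zone2$rank[zone2$compartment == "S"], c(-3L, -2L))
  expect_setequal(zone2$rank[zone2$compartment == "T"], c(2L, 3L))
  expect_error(interface_zone(agg, te_width = 2), "odd")
})

test_that("a region too thin for the requested zone names the missing rank", {
  # epithelium only 2 deep: rank +2 never occurs
  hx <- axial_block(8, 5)
  agg <- make_agg(hx$q, hx$r, epi_frac = as.numeric(hx$q >= 6))
  expect_error(interface_zone(agg), "rank \\+2 empty")
})

test_that("the merged edge separates the epithelial and stromal aspects", {
  skip_if_not_installed("igraph")
  agg <- random_class_map(25, 25, 404)
  zone <- interface_zone(agg)
  key <- zone$q * 1e5 + zone$r
  nb <- hex_neighbors(zone$q, zone$r)
  i <- rep(seq_len(nrow(zone)), each = 6)
  j <- match(nb$nq * 1e5 + nb$nr, key)
  ok <- !is.na(j)
  # drop TE hexagons: no S hexagon may remain connected to a T hexagon
  keep <- zone$compartment != "TE"
  sub <- cbind(i[ok], j[ok])
  sub <- sub[keep[sub[, 1]] & keep[sub[, 2]], , drop = FALSE]
  idx <- which(keep)
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(sub), idx), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  tab <- table(comp, zone$compartment[idx])
  expect_true(all(tab[, "S"] == 0 | tab[, "T"] == 0))
})
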