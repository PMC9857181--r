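# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the code paths they check: the log-rank statistic
# and the Efron partial likelihood are hand-coded, hexagon fixtures are built
# from the closed-form center formula, and graph distances come from igraph.

HEX_SIDE <- 65
HEX_AREA <- (3 * sqrt(3) / 2) * HEX_SIDE^2

# hex_aggregate-shaped tibble from axial coordinates and per-hexagon
# epithelium fraction / CD8 density
make_agg <- function(q, r, epi_frac, density = 0,
                     region_label = "malignant", side = HEX_SIDE) {
  n <- length(q)
  epi_frac <- rep_len(epi_frac, n)
  density <- rep_len(density, n)
  area <- (3 * sqrt(3) / 2) * side^2
  tibble::tibble(
    q = as.integer(q), r = as.integer(r),
    cx_um = 1.5 * side * q,
    cy_um = sqrt(3) * side * (r + q / 2),
    cd8_count = as.integer(round(density * area / 1e6)),
    area_epithelium_um2 = epi_frac * area,
    area_stroma_um2 = (1 - epi_frac) * area,
    area_background_um2 = 0,
    tissue_area_um2 = area,
    tissue_fraction = 1,
    cd8_density_mm2 = density,
    region_label = region_label
  )
}

# parallelogram of axial coordinates
axial_block <- function(nq, nr) {
  expand.grid(q = seq_len(nq) - 1L, r = seq_len(nr) - 1L)
}

# hand-coded two-group log-rank chi-square (no survival:: calls)
oracle_logrank_chi2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    if (n < 2 || d == 0) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  o_minus_e^2 / v
}

# hand-coded Cox partial log-likelihood with the Efron correction for ties
oracle_efron_loglik <- function(beta, x, time, event) {
  x <- as.matrix(x)
  eta <- as.numeric(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(dead)
    sum_risk <- sum(w[risk])
    sum_dead <- sum(w[dead])
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
    }
  }
  ll
}

# signed ranks via igraph shortest paths on the class-restricted hex graph
oracle_ranks_igraph <- function(labeled) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  n <- nrow(labeled)
  key <- labeled$q * 1e5 + labeled$r
  nb <- immunogradient::hex_neighbors(labeled$q, labeled$r)
  tgt <- match(nb$nq * 1e5 + nb$nr, key)
  src <- rep(seq_len(n), each = 6)
  ok <- !is.na(tgt)
  edges <- cbind(src[ok], tgt[ok])
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  cls <- labeled$majority_class
  is_edge_hex <- labeled$edge
  dist_side <- function(side) {
    allowed <- which(cls == side | is_edge_hex)
    sub <- edges[edges[, 1] %in% allowed & edges[, 2] %in% allowed, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(as.vector(sub), allowed), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(allowed) - igraph::vcount(g)))
    dm <- igraph::distances(g, v = match(which(is_edge_hex), allowed))
    d <- apply(dm, 2, min)
    out <- rep(NA_real_, n)
    out[allowed] <- d
    out
  }
  d_epi <- dist_side("epithelium")
  d_str <- dist_side("stroma")
  rank <- ifelse(cls == "stroma", -d_str, d_epi)
  rank[is.infinite(rank)] <- NA
  rank
}

# smooth two-class random hex map with both classes guaranteed adjacent
random_class_map <- function(nq, nr, seed) {
  set.seed(seed)
  hx <- axial_block(nq, nr)
  cx <- 1.5 * hx$q
  cy <- sqrt(3) * (hx$r + hx$q / 2)
  field <- sin(cx / runif(1, 3, 6) + runif(1, 0, 2)) +
    cos(cy / runif(1, 3, 6) + runif(1, 0, 2)) +
    rnorm(nrow(hx), sd = 0.2)
  make_agg(hx$q, hx$r, epi_frac = as.numeric(field > 0))
}

# gradient slide under the frozen study conditions (stromal 200 vs
# epithelial 50 cells/mm^2); returns the computed raw indicator row
gradient_slide_indicators <- function(seed, field_um = 7000, n_blobs = 20,
                                      blob_radius_um = 480, pixel_size_um = 5) {
  tm <- simulate_tissue_map(field_um, field_um, pixel_size_um = pixel_size_um,
                            n_blobs = n_blobs, blob_radius_um = blob_radius_um,
                            seed = seed)
  cells <- simulate_cells(
    tm,
    lambda = c(stroma_far = 200, stroma_near = 200, edge = 100,
               epi_near = 50, epi_far = 50),
    band_width_um = 100, background_negative_lambda = 0, seed = seed + 1)
  m <- field_um - 60
  ann <- region_annotation(
    matrix(c(60, 60, m, 60, m, m, 60, m), ncol = 2, byrow = TRUE), "malignant")
  zone <- interface_zone(hex_aggregate(cells, tm, ann))
  compute_indicators(zone)
}
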