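# Interface-zone construction on the hexagonal grid.
#
# Hexagons are labeled by majority tissue class; the epithelium-stroma edge is
# the set of epithelium-labeled hexagons with at least one stroma-labeled
# neighbor (rank 0). Remaining hexagons get a signed rank equal to their
# hex-graph distance to the nearest edge hexagon, traversed within their own
# class side: positive into epithelium, negative into stroma. The interface
# zone (IZ) keeps a central edge compartment (TE) of `te_width` merged ranks
# flanked by stromal (S) and epithelial (T) compartments of `flank` ranks on
# each side; with the defaults (te_width 3, flank 1) this is a five-rank IZ
# with S = {-2}, TE = {-1, 0, +1}, T = {+2}, re-ranked to positions 1/2/3.

#' Label hexagons by majority tissue class
#'
#' @param aggregates A `hex_aggregate` tibble.
#' @return The input with a `majority_class` column (`"epithelium"` when the
#'   epithelium area is greater than or equal to the stroma area — ties break
#'   toward epithelium — else `"stroma"`).
#' @export
classify_hexes <- function(aggregates) {
  stopifnot(is.data.frame(aggregates))
  aggregates |>
    mutate(majority_class = ifelse(
      .data$area_epithelium_um2 >= .data$area_stroma_um2,
      "epithelium", "stroma"))
}

# neighbor row indices (6 x n matrix; NA where the neighbor is not in the set)
neighbor_index <- function(q, r) {
  keys <- hex_key(q, r)
  nb <- hex_neighbors(q, r)
  matrix(match(hex_key(nb$nq, nb$nr), keys), nrow = 6)
}

#' Extract the epithelium-stroma edge (rank-0 hexagons)
#'
#' @param labeled A `hex_aggregate` tibble with a `majority_class` column
#'   (see [classify_hexes()]).
#' @return The input with a logical `edge` column marking epithelium-labeled
#'   hexagons that touch at least one stroma-labeled hexagon.
#' @export
extract_edge <- function(labeled) {
  if (!"majority_class" %in% names(labeled)) labeled <- classify_hexes(labeled)
  cls <- labeled$majority_class
  if (length(unique(cls)) < 2) abort("no interface detected: single-class region")
  nb <- neighbor_index(labeled$q, labeled$r)
  touches_stroma <- apply(nb, 2, function(ix) {
    ix <- ix[!is.na(ix)]
    any(cls[ix] == "stroma")
  })
  labeled$edge <- cls == "epithelium" & touches_stroma
  if (!any(labeled$edge)) abort("no interface detected: classes not adjacent")
  labeled
}

#' Assign signed interface ranks by breadth-first search
#'
#' Multi-source BFS from the edge hexagons over the hex adjacency graph
#' restricted to each class side: epithelium hexagons receive `+d`, stroma
#' hexagons `-d`, where `d` is the graph distance to the nearest edge
#' hexagon. Hexagons unreachable from the edge within their class side (e.g.
#' an epithelial island that nowhere touches stroma inside the region) get
#' `NA` rank.
#'
#' @param labeled A `hex_aggregate` tibble; [classify_hexes()] and
#'   [extract_edge()] are applied if their columns are absent.
#' @return The input tibble with `edge` and integer `rank` columns.
#' @export
assign_ranks <- function(labeled) {
  if (!"edge" %in% names(labeled)) labeled <- extract_edge(labeled)
  n <- nrow(labeled)
  cls <- labeled$majority_class
  nb <- neighbor_index(labeled$q, labeled$r)
  dist <- rep(NA_integer_, n)
  dist[labeled$edge] <- 0L
  for (side in c("epithelium", "stroma")) {
    frontier <- which(labeled$edge)
    d <- 0L
    while (length(frontier) > 0) {
      d <- d + 1L
      cand <- unique(as.integer(nb[, frontier]))
      cand <- cand[!is.na(cand)]
      cand <- cand[cls[cand] == side & is.na(dist[cand])]
      dist[cand] <- d
      frontier <- cand
    }
  }
  labeled$rank <- ifelse(cls == "stroma", -dist, dist)
  labeled
}

#' Build the interface zone with S / TE / T compartments
#'
#' @param ranked A tibble with `rank` (from [assign_ranks()]); a plain
#'   `hex_aggregate` is ranked first.
#' @param te_width Width of the central edge compartment in ranks (odd,
#'   default 3: ranks -1, 0, +1 merged into TE).
#' @param flank Number of ranks in each flanking compartment (default 1:
#'   S = rank -2, T = rank +2, a five-rank interface zone).
#' @return A tibble of class `interface_zone`: the IZ member hexagons with
#'   `compartment` (`"S"`, `"TE"`, `"T"`) and `position` (1, 2, 3, the
#'   re-ranked coordinate used by the center-of-mass indicator). Attributes
#'   `te_width` and `flank` record the configuration.
#' @export
build_interface_zone <- function(ranked, te_width = 3, flank = 1) {
  if (te_width < 1 || te_width %% 2 != 1) abort("`te_width` must be odd and >= 1.")
  if (flank < 1) abort("`flank` must be >= 1.")
  if (!"rank" %in% names(ranked)) ranked <- assign_ranks(ranked)
  half <- (te_width - 1) / 2
  depth <- half + flank
  for (rk in seq(-depth, depth)) {
    if (!any(!is.na(ranked$rank) & ranked$rank == rk)) {
      abort(sprintf("rank %+d empty: region too thin for the requested interface zone", rk))
    }
  }
  zone <- ranked |>
    filter(!is.na(.data$rank), abs(.data$rank) <= depth) |>
    mutate(
      compartment = case_when(
        .data$rank < -half ~ "S",
        .data$rank > half ~ "T",
        TRUE ~ "TE"
      ),
      position = c(S = 1, TE = 2, T = 3)[.data$compartment]
    )
  attr(zone, "te_width") <- te_width
  attr(zone, "flank") <- flank
  class(zone) <- c("interface_zone", class(zone))
  zone
}

#' Full interface-zone construction from hexagon aggregates
#'
#' Convenience chain: [classify_hexes()], [extract_edge()], [assign_ranks()],
#' [build_interface_zone()].
#'
#' @inheritParams build_interface_zone
#' @param aggregates A `hex_aggregate` tibble.
#' @return An `interface_zone` tibble.
#' @export
interface_zone <- function(aggregates, te_width = 3, flank = 1) {
  aggregates |>
    classify_hexes() |>
    extract_edge() |>
    assign_ranks() |>
    build_interface_zone(te_width = te_width, flank = flank)
}
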