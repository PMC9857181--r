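# Immunogradient indicators computed from the interface zone.
#
# Per compartment (S, TE, T): mean (m) and sample standard deviation (sd) of
# the per-hexagon marker density in cells/mm^2. Whole-IZ indicators:
#   CM  = sum(position * value) / sum(value) over positions (1, 2, 3)
#         computed once with the compartment means (CM_m) and once with the
#         standard deviations (CM_sd); range [1, 3], > 2 means the mass is
#         shifted toward the epithelial aspect.
#   ID  = m(S) / m(T), the "immunodrop": > 1 signals an abrupt density drop
#         from the stromal to the epithelial aspect across the edge.
# Indicators are natural-log transformed for parametric statistics; zero
# densities receive a pseudo-count of `eps` cells/mm^2 before the log.

#' Per-compartment density statistics
#'
#' @param zone An `interface_zone` tibble carrying `cd8_density_mm2` per
#'   hexagon (hexagons whose density is `NA` — below the tissue-area floor —
#'   are excluded).
#' @return A tibble with one row per compartment (`S`, `TE`, `T`): `m`
#'   (mean density, cells/mm^2), `sd` (sample standard deviation, 0 for a
#'   single hexagon) and `n_hex`.
#' @export
compartment_stats <- function(zone) {
  stopifnot(is.data.frame(zone), all(c("compartment", "cd8_density_mm2") %in% names(zone)))
  usable <- zone |> filter(!is.na(.data$cd8_density_mm2))
  for (cp in c("S", "TE", "T")) {
    if (!any(usable$compartment == cp)) {
      abort(sprintf("compartment %s is empty after the tissue-area filter", cp))
    }
  }
  usable |>
    group_by(.data$compartment) |>
    summarise(
      m = mean(.data$cd8_density_mm2),
      sd = if (n() > 1) stats::sd(.data$cd8_density_mm2) else 0,
      n_hex = n(),
      .groups = "drop"
    ) |>
    mutate(compartment = factor(.data$compartment, levels = c("S", "TE", "T"))) |>
    arrange(.data$compartment) |>
    mutate(compartment = as.character(.data$compartment))
}

#' Center of mass of a compartment profile
#'
#' @param values Non-negative values per compartment (e.g. the three
#'   compartment means).
#' @param positions Compartment positions (default 1 = S, 2 = TE, 3 = T).
#' @return `sum(positions * values) / sum(values)`; `NA` when all values are
#'   zero.
#' @export
center_of_mass <- function(values, positions = c(1, 2, 3)) {
  stopifnot(length(values) == length(positions))
  if (any(values < 0, na.rm = TRUE)) abort("`values` must be non-negative.")
  tot <- sum(values)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(positions * values) / tot
}

#' Immunodrop ratio
#'
#' @param m_s Mean density in the stromal aspect (re-rank position 1).
#' @param m_t Mean density in the epithelial aspect (re-rank position 3).
#' @return `m_s / m_t`; `NA` when `m_t` is zero (not infinity).
#' @export
immunodrop <- function(m_s, m_t) {
  if (is.na(m_s) || is.na(m_t) || m_t == 0) return(NA_real_)
  m_s / m_t
}

#' Compute the immunogradient indicator set for one interface zone
#'
#' @param zone An `interface_zone` tibble (see [interface_zone()]).
#' @return A one-row tibble: `region_label`, compartment densities `m_S`,
#'   `m_TE`, `m_T`, `sd_S`, `sd_TE`, `sd_T` (cells/mm^2), and the whole-zone
#'   indicators `CM_m`, `CM_sd`, `ID` (dimensionless).
#' @export
compute_indicators <- function(zone) {
  st <- compartment_stats(zone)
  m <- setNames(st$m, st$compartment)
  s <- setNames(st$sd, st$compartment)
  region <- unique(zone$region_label)
  tibble(
    region_label = if (length(region) == 1) region else NA_character_,
    m_S = m[["S"]], m_TE = m[["TE"]], m_T = m[["T"]],
    sd_S = s[["S"]], sd_TE = s[["TE"]], sd_T = s[["T"]],
    CM_m = center_of_mass(unname(m[c("S", "TE", "T")])),
    CM_sd = center_of_mass(unname(s[c("S", "TE", "T")])),
    ID = immunodrop(m[["S"]], m[["T"]])
  )
}

INDICATOR_NAMES <- c("m_S", "m_TE", "m_T", "sd_S", "sd_TE", "sd_T",
                     "CM_m", "CM_sd", "ID")

#' Natural-log transform of an indicator table
#'
#' Applies `log()` to each indicator column. Zero-valued density indicators
#' (the `m_*` and `sd_*` columns, in cells/mm^2) receive a pseudo-count of
#' `eps` before the log, so a zero density maps to `log(eps)` (0 for the
#' default `eps = 1`). The dimensionless `CM_*` and `ID` columns are logged
#' directly.
#'
#' @param indicators A tibble with indicator columns as produced by
#'   [compute_indicators()] (any subset of them).
#' @param eps Pseudo-count in cells/mm^2 added to zero densities (default 1).
#' @return The tibble with indicator columns replaced by their natural logs.
#' @export
log_transform_indicators <- function(indicators, eps = 1) {
  dens <- intersect(names(indicators),
                    c("m_S", "m_TE", "m_T", "sd_S", "sd_TE", "sd_T"))
  ratio <- intersect(names(indicators), c("CM_m", "CM_sd", "ID"))
  indicators |>
    mutate(
      across(all_of(dens), ~ log(ifelse(.x == 0, eps, .x))),
      across(all_of(ratio), ~ log(.x))
    )
}

#' Pivot per-region indicator rows to prefixed wide columns
#'
#' Maps the region labels to the column-name prefixes used in reported
#' indicator tables: `malignant` regions get the prefix `HCC_`,
#' `non_malignant` regions `Liver_` (e.g. `HCC_sd_TE`, `Liver_m_T`).
#'
#' @param indicators A tibble of indicator rows with a `region_label` column
#'   (and optionally `patient_id`).
#' @return A tibble with one row per patient (or a single row) and columns
#'   `<prefix>_<indicator>`.
#' @export
indicator_wide <- function(indicators) {
  prefix <- c(malignant = "HCC", non_malignant = "Liver")
  long <- indicators |>
    mutate(ind_prefix = prefix[.data$region_label]) |>
    select(-"region_label") |>
    tidyr::pivot_longer(cols = any_of(INDICATOR_NAMES),
                        names_to = "ind_name", values_to = "ind_value") |>
    mutate(ind_name = paste(.data$ind_prefix, .data$ind_name, sep = "_")) |>
    select(-"ind_prefix")
  if ("patient_id" %in% names(long)) {
    tidyr::pivot_wider(long, id_cols = "patient_id",
                       names_from = "ind_name", values_from = "ind_value")
  } else {
    tidyr::pivot_wider(long, names_from = "ind_name", values_from = "ind_value")
  }
}

#' Indicators for one slide, all annotated regions
#'
#' Runs the hexagonal aggregation, interface-zone construction and indicator
#' extraction for each region label present in the annotation.
#'
#' @param cells Cell tibble (`x_um`, `y_um`, `cd8_positive`).
#' @param tissue A [tissue_map()].
#' @param annotation A region annotation tibble.
#' @param side_um Hexagon side length in micrometers (default 65).
#' @param te_width,flank Interface-zone configuration (see
#'   [build_interface_zone()]).
#' @param min_tissue_fraction Tissue-area floor for density hexagons.
#' @param log_scale Also append natural-log columns? If `TRUE` (default) the
#'   returned indicators are on the log scale; raw densities are kept with a
#'   `raw_` prefix in the attribute `raw`.
#' @param eps Pseudo-count for the log transform.
#' @return A tibble with one row per annotated region: `region_label` plus
#'   the indicator columns (log scale when `log_scale = TRUE`).
#' @export
slide_indicators <- function(cells, tissue, annotation, side_um = 65,
                             te_width = 3, flank = 1,
                             min_tissue_fraction = 0.1,
                             log_scale = TRUE, eps = 1) {
  annotation <- validate_annotation(annotation)
  rows <- purrr::map(unique(annotation$label), function(lab) {
    agg <- hex_aggregate(cells, tissue, annotation, region_label = lab,
                         min_tissue_fraction = min_tissue_fraction)
    zone <- interface_zone(agg, te_width = te_width, flank = flank)
    compute_indicators(zone)
  })
  out <- list_rbind(rows)
  if (log_scale) out <- log_transform_indicators(out, eps = eps)
  out
}
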