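# End-to-end study pipeline with on-disk intermediates:
#   simulate_study()      -> study directory (per-patient slide triads + cohort)
#   run_indicators()      -> per-patient indicator table (both interfaces)
#   run_survival()        -> univariate cutoff tables, stepwise models, LOOCV
#   run_score()           -> combined risk scores + stratified survival
#   run_study_pipeline()  -> all of the above, with resolved config and logs
# Each stage reads and writes the documented CSV/PNG/GeoJSON/JSON formats, so
# stages are independently testable and replaceable by real segmentation
# exports.

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis in one list: hexagon side length
#' (65 um), interface-zone shape (3-rank central edge, 1-rank flanks: a
#' five-rank IZ), the tissue-area density floor, the log-transform
#' pseudo-count, the cutoff group-size floor, stepwise entry/removal alphas,
#' the LOOCV frequency threshold and the survival horizons (24 and 60
#' months).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    side_um = 65,
    te_width = 3,
    flank = 1,
    min_tissue_fraction = 0.1,
    log_eps = 1,
    min_group_fraction = 0.1,
    alpha_enter = 0.05,
    alpha_remove = 0.10,
    loocv_threshold = 0.5,
    horizons = c(24, 60),
    pixel_size_um = 2.5
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  modifyList(cfg, overrides)
}

write_stage_config <- function(dir, cfg, extra = list()) {
  stamp <- c(cfg, extra,
             list(package_version = as.character(utils::packageVersion("immunogradient"))))
  jsonlite::write_json(stamp, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a complete study directory
#'
#' Generates one slide per patient: a tissue-class raster whose left half is
#' the malignant region and right half the perineoplastic (non-malignant)
#' region, each populated with epithelial blobs; CD8+/- cell centroids with a
#' density gradient across the epithelium-stroma interface; a GeoJSON
#' annotation of the two regions; and a clinical cohort CSV whose survival
#' endpoints follow a Weibull proportional-hazards model linked to the true
#' (generative) per-patient epithelial CD8 intensities — high CD8 density in
#' the non-malignant epithelium worsens survival, high density at the
#' malignant interface improves it.
#'
#' @param out_dir Study directory to create.
#' @param n_patients Number of patients/slides (default 20).
#' @param config A [pipeline_config()] list.
#' @param field_um Width/height of each half-field in micrometers
#'   (default 1400).
#' @param beta Named log hazard ratios on the true log intensities
#'   `true_log_hcc` and `true_log_liver`.
#' @param censoring_rate Target censoring fraction.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return `out_dir`, invisibly.
#' @export
simulate_study <- function(out_dir, n_patients = 20,
                           config = pipeline_config(),
                           field_um = 1400,
                           beta = c(true_log_liver = 1.0, true_log_hcc = -0.7),
                           censoring_rate = 0.35,
                           seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "slides"), showWarnings = FALSE)
  px <- config$pixel_size_um
  margin <- 60
  half_w <- field_um
  h <- field_um
  base_epi <- 60
  base_str <- 240

  with_seed(seed, {
    u_hcc <- rnorm(n_patients, 0, 0.5)
    u_liver <- rnorm(n_patients, 0, 0.5)
    slide_seeds <- sample.int(2^30, 2 * n_patients)
  })
  truth <- tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    true_log_hcc = log(base_epi) + u_hcc,
    true_log_liver = log(base_epi) + u_liver
  )

  for (i in seq_len(n_patients)) {
    pid <- truth$patient_id[i]
    sdir <- file.path(out_dir, "slides", pid)
    dir.create(sdir, showWarnings = FALSE)
    half <- function(u, s_tis, s_cells) {
      tm <- simulate_tissue_map(half_w, h, pixel_size_um = px, n_blobs = 2,
                                blob_radius_um = 330, radius_jitter_um = 30,
                                n_lobes = 3, seed = s_tis)
      lam_epi <- base_epi * exp(u)
      cells <- simulate_cells(
        tm,
        lambda = c(stroma_far = base_str, stroma_near = base_str,
                   edge = sqrt(base_str * lam_epi),
                   epi_near = lam_epi, epi_far = lam_epi),
        band_width_um = 100, background_negative_lambda = 400,
        seed = s_cells)
      list(tm = tm, cells = cells)
    }
    mal <- half(u_hcc[i], slide_seeds[2 * i - 1], slide_seeds[2 * i - 1] + 1L)
    non <- half(u_liver[i], slide_seeds[2 * i], slide_seeds[2 * i] + 1L)
    labels <- cbind(mal$tm$labels, non$tm$labels)
    tm_full <- tissue_map(labels, px)
    cells <- bind_rows(
      mal$cells,
      non$cells |> mutate(x_um = .data$x_um + half_w)
    )
    rect <- function(x0, x1, y0, y1) {
      matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
    }
    ann <- region_annotation(
      list(rect(margin, half_w - margin, margin, h - margin),
           rect(half_w + margin, 2 * half_w - margin, margin, h - margin)),
      label = c("malignant", "non_malignant")
    )
    write_tissue_map(tm_full, file.path(sdir, "tissue.png"))
    write_cells(cells, file.path(sdir, "cells.csv"))
    write_annotations(ann, file.path(sdir, "annotations.geojson"))
  }

  cohort <- simulate_cohort(
    covariates = truth,
    beta = beta, beta_rfs = beta,
    baseline_shape = 1.2, baseline_scale = 60,
    censoring_rate = censoring_rate, round_months = TRUE,
    seed = seed + 1L
  )
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_stage_config(out_dir, config,
                     list(stage = "simulate", n_patients = n_patients,
                          field_um = field_um, seed = seed,
                          beta = as.list(beta), censoring_rate = censoring_rate))
  invisible(out_dir)
}

#' Compute indicator tables for every slide of a study
#'
#' Reads each slide triad (cells CSV, tissue PNG, annotation GeoJSON) and
#' computes the log-scale immunogradient indicators for every annotated
#' region. A slide whose annotation lacks one region (e.g. no perineoplastic
#' parenchyma present) yields `NA` for that region's indicators, with a log
#' message; a region too thin for the configured interface zone is treated
#' the same way.
#'
#' @param study_dir Study directory (see [simulate_study()]).
#' @param config A [pipeline_config()] list.
#' @param out_dir Where to write `indicators.csv` and the resolved config
#'   (default `<study_dir>/results`).
#' @return A tibble with one row per patient and prefixed indicator columns
#'   (`HCC_*` for malignant, `Liver_*` for non-malignant interfaces).
#' @export
run_indicators <- function(study_dir, config = pipeline_config(),
                           out_dir = file.path(study_dir, "results")) {
  slide_dirs <- sort(list.dirs(file.path(study_dir, "slides"), recursive = FALSE))
  if (length(slide_dirs) == 0) abort(sprintf("no slides found under %s", study_dir))
  rows <- purrr::map(slide_dirs, function(sdir) {
    pid <- basename(sdir)
    cells <- read_cells(file.path(sdir, "cells.csv"))
    tissue <- tryCatch(
      read_tissue_map(file.path(sdir, "tissue.png"), config$pixel_size_um),
      error = function(e) abort(sprintf("corrupted or unreadable raster %s: %s",
                                        file.path(sdir, "tissue.png"),
                                        conditionMessage(e))))
    ann <- read_annotations(file.path(sdir, "annotations.geojson"))
    region_rows <- purrr::map(REGION_LABELS, function(lab) {
      if (!lab %in% ann$label) {
        inform(sprintf("%s: no '%s' annotation; indicators set to NA", pid, lab))
        return(tibble(region_label = lab))
      }
      tryCatch({
        agg <- hex_aggregate(cells, tissue, ann, region_label = lab,
                             min_tissue_fraction = config$min_tissue_fraction)
        zone <- interface_zone(agg, te_width = config$te_width,
                               flank = config$flank)
        compute_indicators(zone) |>
          log_transform_indicators(eps = config$log_eps)
      }, error = function(e) {
        inform(sprintf("%s/%s: %s; indicators set to NA", pid, lab,
                       conditionMessage(e)))
        tibble(region_label = lab)
      })
    }) |> list_rbind()
    region_rows$patient_id <- pid
    region_rows
  }) |> list_rbind()
  for (ind in INDICATOR_NAMES) {
    if (!ind %in% names(rows)) rows[[ind]] <- NA_real_
  }
  wide <- indicator_wide(rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(wide, file.path(out_dir, "indicators.csv"))
  write_stage_config(out_dir, config, list(stage = "indicators"))
  wide
}

#' Survival modeling stage
#'
#' For each endpoint (overall survival and recurrence-free survival):
#' an optimal-cutoff univariate screen over the candidate variables, then
#' stepwise-LR Cox selection over the dichotomized variables that reached
#' nominal univariate significance, and leave-one-out selection stability.
#'
#' @param indicators Indicator tibble from [run_indicators()] (or a CSV path).
#' @param cohort Cohort tibble from [read_cohort()] (or a CSV path).
#' @param config A [pipeline_config()] list.
#' @param candidates Character vector of continuous candidate variables;
#'   defaults to every indicator column plus every numeric cohort covariate.
#' @param out_dir Optional output directory for CSV/JSON results.
#' @return A list with one element per endpoint (`os`, `rfs`), each a list
#'   `univariate` (cutoff screen tibble), `model` (stepwise `ig_cox`),
#'   `stability` (`stability_report` or `NULL` when fewer than 10 complete
#'   cases), and `data` (the merged analysis tibble with `_hi` columns).
#' @export
run_survival <- function(indicators, cohort, config = pipeline_config(),
                         candidates = NULL, out_dir = NULL) {
  if (is.character(indicators)) indicators <- readr::read_csv(
    indicators, col_types = readr::cols(), show_col_types = FALSE)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  d <- left_join(cohort, indicators, by = "patient_id")
  reserved <- c("patient_id", "os_months", "os_event", "rfs_months", "rfs_event")
  if (is.null(candidates)) {
    candidates <- setdiff(names(d), reserved)
    candidates <- candidates[vapply(d[candidates], is.numeric, logical(1))]
    candidates <- candidates[!startsWith(candidates, "true_")]
  }
  endpoints <- list(os = c("os_months", "os_event"),
                    rfs = c("rfs_months", "rfs_event"))
  out <- purrr::imap(endpoints, function(ep, nm) {
    uni <- univariate_cutoff_screen(d, candidates, ep[1], ep[2],
                                    min_group_fraction = config$min_group_fraction)
    dd <- apply_cutoffs(d, uni)
    sig <- if (nrow(uni) > 0) uni$variable[uni$p_value < 0.05] else character()
    cand_hi <- if (length(sig) > 0) paste0(sig, "_hi") else character()
    model <- if (length(cand_hi) > 0) {
      stepwise_cox(dd, ep[1], ep[2], cand_hi,
                   alpha_enter = config$alpha_enter,
                   alpha_remove = config$alpha_remove)
    } else cox_fit(dd, ep[1], ep[2], character())
    stability <- if (length(cand_hi) > 0 &&
                     sum(complete.cases(dd[, c(cand_hi, ep)])) >= 10) {
      tryCatch(
        loocv_stability(dd, ep[1], ep[2], cand_hi,
                        alpha_enter = config$alpha_enter,
                        alpha_remove = config$alpha_remove,
                        freq_threshold = config$loocv_threshold),
        error = function(e) NULL)
    } else NULL
    list(univariate = uni, model = model, stability = stability, data = dd)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      readr::write_csv(out[[nm]]$univariate,
                       file.path(out_dir, sprintf("univariate_%s.csv", nm)))
      model_json <- list(
        variables = tidy(out[[nm]]$model),
        model = glance(out[[nm]]$model),
        stability = if (!is.null(out[[nm]]$stability))
          tidy(out[[nm]]$stability) else NULL
      )
      jsonlite::write_json(model_json,
                           file.path(out_dir, sprintf("model_%s.json", nm)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    write_stage_config(out_dir, config, list(stage = "survival"))
  }
  out
}

#' Risk-score stage
#'
#' Builds poor-prognosis rules from the selected overall-survival model (rule
#' direction from each term's hazard-ratio sign, cutoff from the univariate
#' screen), assigns the combined score, and stratifies survival into
#' low / intermediate / high tiers. When stepwise selection retained fewer
#' than two variables, the two univariate variables with the largest log-rank
#' chi-square are used as a deterministic fallback so a score is always
#' defined.
#'
#' @param survival_results Output of [run_survival()].
#' @param config A [pipeline_config()] list.
#' @param endpoint Which endpoint's model drives the rules (default `"os"`).
#' @param out_dir Optional output directory.
#' @return A list: `rules`, `scores` (a `risk_score` tibble), `strata`
#'   (a `risk_strata` object, or `NULL` when fewer than two tiers are
#'   populated).
#' @export
run_score <- function(survival_results, config = pipeline_config(),
                      endpoint = "os", out_dir = NULL) {
  res <- survival_results[[endpoint]]
  uni <- res$univariate
  model <- res$model
  if (length(model$variables) >= 2) {
    rules <- rules_from_model(model, uni)
  } else {
    if (nrow(uni) < 2) abort("need at least two candidate variables to build a score")
    top <- uni |> arrange(desc(.data$logrank_chi2)) |> slice(1:2)
    rules <- risk_rules(top$variable, top$cutoff,
                        ifelse(top$hr > 1, "above", "below"))
    inform("fewer than two variables in the selected model; using the top two univariate predictors")
  }
  scores <- assign_risk_score(res$data, rules)
  scored <- left_join(res$data, scores[, c("patient_id", "score", "category")],
                      by = "patient_id")
  ep <- if (endpoint == "os") c("os_months", "os_event") else c("rfs_months", "rfs_event")
  strata <- tryCatch(
    stratified_survival(scored, ep[1], ep[2], "category",
                        horizons = config$horizons),
    error = function(e) {
      inform(sprintf("stratified survival unavailable: %s", conditionMessage(e)))
      NULL
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(as_tibble(rules), file.path(out_dir, "rules.csv"))
    readr::write_csv(scores |> mutate(category = as.character(.data$category)),
                     file.path(out_dir, "scores.csv"))
    if (!is.null(strata)) {
      jsonlite::write_json(
        list(survival_at = strata$survival_at, pairwise = strata$pairwise,
             n = strata$n),
        file.path(out_dir, "strata.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }
    write_stage_config(out_dir, config, list(stage = "score"))
  }
  list(rules = rules, scores = scores, strata = strata)
}

#' Run the full pipeline on a study directory
#'
#' Chains [run_indicators()], [run_survival()] and [run_score()], writing all
#' intermediates and the resolved configuration under
#' `<study_dir>/results`.
#'
#' @param study_dir Study directory with `slides/` and `cohort.csv`.
#' @param config A [pipeline_config()] list.
#' @return A list with `indicators`, `survival`, `score`.
#' @export
run_study_pipeline <- function(study_dir, config = pipeline_config()) {
  out_dir <- file.path(study_dir, "results")
  ind <- run_indicators(study_dir, config, out_dir = out_dir)
  cohort <- read_cohort(file.path(study_dir, "cohort.csv"))
  surv <- run_survival(ind, cohort, config, out_dir = out_dir)
  score <- run_score(surv, config, out_dir = out_dir)
  list(indicators = ind, survival = surv, score = score)
}
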