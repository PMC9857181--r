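# Combined prognostic score: each independent predictor contributes 1 for a
# poor-prognosis value and 0 otherwise; the integer sum stratifies patients
# into low / intermediate / high risk tiers.

#' Define a set of prognostic scoring rules
#'
#' Each rule dichotomizes one variable at a cutoff; `poor_when` states which
#' side of the cutoff carries the poor-prognosis point. When building rules
#' from a multivariable Cox model of dichotomized (high = 1) predictors, a
#' hazard ratio above 1 means high values are poor (`poor_when = "above"`)
#' and below 1 that high values are good (`poor_when = "below"`); see
#' [rules_from_model()].
#'
#' @param variable Character vector of variable names.
#' @param cutoff Numeric vector of cutoffs.
#' @param poor_when `"above"` (value > cutoff scores 1) or `"below"`
#'   (value <= cutoff scores 1); recycled.
#' @return A tibble of class `risk_rules` with columns `variable`, `cutoff`,
#'   `poor_when`.
#' @export
risk_rules <- function(variable, cutoff, poor_when) {
  poor_when <- rep_len(poor_when, length(variable))
  if (!all(poor_when %in% c("above", "below"))) {
    abort('`poor_when` must be "above" or "below"')
  }
  out <- tibble(variable = variable, cutoff = as.numeric(cutoff),
                poor_when = poor_when)
  class(out) <- c("risk_rules", class(out))
  out
}

#' Derive scoring rules from a multivariable Cox model
#'
#' For a model whose covariates are 0/1 indicators of "value above cutoff"
#' (as produced by [apply_cutoffs()]), each term's rule direction follows the
#' sign of its log hazard ratio: HR > 1 means the high side is poor.
#'
#' @param model An `ig_cox` fit of dichotomized covariates named
#'   `<variable><suffix>`.
#' @param cutoffs A `cutoff_result` tibble supplying `variable` and `cutoff`.
#' @param suffix Suffix used when dichotomizing (default `"_hi"`).
#' @return A `risk_rules` tibble.
#' @export
rules_from_model <- function(model, cutoffs, suffix = "_hi") {
  td <- tidy(model)
  base <- sub(paste0(suffix, "$"), "", td$term)
  ct <- cutoffs$cutoff[match(base, cutoffs$variable)]
  if (any(is.na(ct))) {
    abort(sprintf("no cutoff found for term(s): %s",
                  paste(base[is.na(ct)], collapse = ", ")))
  }
  risk_rules(base, ct, ifelse(td$estimate > 0, "above", "below"))
}

#' Assign combined prognostic scores
#'
#' Sums the 0/1 poor-prognosis contributions of each rule per patient and
#' maps the total to a risk category. Patients missing any rule variable get
#' an `NA` score and category (complete-case scoring); they are flagged in
#' the `scored` column.
#'
#' @param data A data frame with one row per patient, containing the rule
#'   variables (on the same scale as the rule cutoffs).
#' @param rules A `risk_rules` tibble.
#' @param id Column name of the patient identifier (default `"patient_id"`;
#'   created as the row number when absent).
#' @param breaks Two integers: the maximum score of the low tier and of the
#'   intermediate tier. The default `c(1, 2)` maps scores 0-1 to low, 2 to
#'   intermediate and 3+ to high (for a five-rule score, 3-5).
#' @return A tibble of class `risk_score`: `patient_id`, one 0/1 column per
#'   rule (named `<variable>_poor`), `score`, `category` (factor
#'   low/intermediate/high) and `scored`.
#' @export
assign_risk_score <- function(data, rules, id = "patient_id",
                              breaks = c(1, 2)) {
  stopifnot(is.data.frame(data), inherits(rules, "risk_rules"))
  if (length(breaks) != 2 || breaks[1] >= breaks[2]) {
    abort("`breaks` must be two increasing integers (low max, intermediate max)")
  }
  missing_vars <- setdiff(rules$variable, names(data))
  if (length(missing_vars) > 0) {
    abort(sprintf("rule variable(s) absent from data: %s",
                  paste(missing_vars, collapse = ", ")))
  }
  out <- tibble(patient_id = if (id %in% names(data)) data[[id]]
                else as.character(seq_len(nrow(data))))
  for (i in seq_len(nrow(rules))) {
    v <- rules$variable[i]
    hi <- data[[v]] > rules$cutoff[i]
    poor <- if (rules$poor_when[i] == "above") hi else !hi
    out[[paste0(v, "_poor")]] <- as.integer(poor)
  }
  poor_cols <- paste0(rules$variable, "_poor")
  out$score <- rowSums(out[, poor_cols, drop = FALSE])
  out$scored <- !is.na(out$score)
  if (any(!out$scored)) {
    inform(sprintf("%d patient(s) excluded from scoring (missing rule variables): %s",
                   sum(!out$scored),
                   paste(head(out$patient_id[!out$scored], 10), collapse = ", ")))
  }
  out$category <- factor(
    ifelse(is.na(out$score), NA_character_,
           ifelse(out$score <= breaks[1], "low",
                  ifelse(out$score <= breaks[2], "intermediate", "high"))),
    levels = c("low", "intermediate", "high")
  )
  class(out) <- c("risk_score", class(out))
  out
}

#' Two-predictor immune-only risk score
#'
#' The reduced score built from the two interface-zone CD8 density-profile
#' predictors alone (one per region interface). Scores 0 / 1 / 2 map to
#' low / intermediate / high.
#'
#' @inheritParams assign_risk_score
#' @param rules A `risk_rules` tibble with exactly two rules.
#' @return A `risk_score` tibble (scores 0-2).
#' @export
cd8_risk_score <- function(data, rules, id = "patient_id") {
  if (nrow(rules) != 2) abort("the CD8-only score uses exactly two rules")
  assign_risk_score(data, rules, id = id, breaks = c(0, 1))
}

#' Survival stratified by risk category
#'
#' Kaplan-Meier curves per risk tier, pairwise log-rank comparisons, and
#' survival probabilities at fixed horizons.
#'
#' @param data A data frame containing the endpoint columns and a risk
#'   category column (e.g. the output of joining [assign_risk_score()] back
#'   to the cohort).
#' @param time,event Column names of follow-up time and 0/1 event flag.
#' @param category Column name of the risk tier (default `"category"`).
#' @param horizons Months at which to report survival probabilities
#'   (default 24 and 60).
#' @return An object of class `risk_strata`: list with `km` (a `km_curve`),
#'   `survival_at` (tibble of category, time, survival), `pairwise`
#'   (pairwise log-rank tibble), `n` (per-category counts).
#' @export
stratified_survival <- function(data, time, event, category = "category",
                                horizons = c(24, 60)) {
  d <- data[!is.na(data[[category]]), , drop = FALSE]
  d[[category]] <- droplevels(as.factor(d[[category]]))
  counts <- d |> count(.data[[category]], name = "n")
  if (nrow(counts) < 2) abort("need at least 2 non-empty risk categories")
  km <- kaplan_meier(d, time, event, group = category)
  out <- list(
    km = km,
    survival_at = km_survival_at(km, horizons) |>
      rename(category = "group"),
    pairwise = pairwise_logrank(d, time, event, category),
    n = counts,
    time = time, event = event, horizons = horizons
  )
  class(out) <- "risk_strata"
  out
}

#' @export
print.risk_strata <- function(x, ...) {
  cat("<risk_strata>\n")
  print(x$survival_at)
  print(x$pairwise)
  invisible(x)
}

#' @rdname stratified_survival
#' @param x A `risk_strata` object.
#' @param ... Unused.
#' @method tidy risk_strata
#' @export
tidy.risk_strata <- function(x, ...) x$survival_at

#' @rdname stratified_survival
#' @method glance risk_strata
#' @export
glance.risk_strata <- function(x, ...) {
  tibble(n_categories = nrow(x$n), n_total = sum(x$n$n),
         min_pairwise_p = min(x$pairwise$p_value),
         max_pairwise_p = max(x$pairwise$p_value))
}
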