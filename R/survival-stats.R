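# Outcome statistics: Kaplan-Meier estimation, log-rank testing and
# log-rank-optimal cutoff dichotomization of continuous indicators.
# Estimation itself is delegated to the `survival` package; the cutoff scan
# (exhaustive over admissible candidate midpoints, maximizing the log-rank
# chi-square subject to a minimum group-size floor) is implemented here.

surv_formula <- function(time, event, rhs = "1") {
  stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, rhs))
}

#' Kaplan-Meier survivor-function estimate
#'
#' @param data A data frame.
#' @param time,event Column names (strings) of the follow-up time and the
#'   0/1 event flag.
#' @param group Optional column name of a grouping factor.
#' @return A tibble of class `km_curve` with columns `group` (if any),
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `lower`, `upper`.
#' @export
#' @examples
#' coh <- simulate_cohort(80, covariate_probs = c(arm = 0.5),
#'                        beta = c(arm = log(2)), seed = 7)
#' km <- kaplan_meier(coh, "os_months", "os_event", group = "arm")
#' km_survival_at(km, c(24, 60))
kaplan_meier <- function(data, time = "os_months", event = "os_event",
                         group = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) abort("empty input")
  if (any(data[[time]] <= 0, na.rm = TRUE)) abort("times must be > 0")
  rhs <- if (is.null(group)) "1" else group
  fit <- survival::survfit(surv_formula(time, event, rhs), data = data)
  sm <- summary(fit, censored = TRUE)
  out <- tibble(
    group = if (is.null(group)) NA_character_
            else sub("^[^=]*=", "", as.character(sm$strata)),
    time = sm$time,
    n_risk = sm$n.risk,
    n_event = sm$n.event,
    n_censor = sm$n.censor,
    survival = sm$surv,
    lower = sm$lower,
    upper = sm$upper
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Query a Kaplan-Meier curve at given times
#'
#' Step-function evaluation of the product-limit estimate (survival is 1
#' before the first event time).
#'
#' @param km A `km_curve` tibble.
#' @param times Times at which to evaluate the survivor function.
#' @return A tibble with `group`, `time` and `survival`.
#' @export
km_survival_at <- function(km, times) {
  km |>
    group_by(.data$group) |>
    group_modify(function(gd, key) {
      f <- stats::stepfun(gd$time, c(1, gd$survival), right = FALSE)
      tibble(time = times, survival = f(times))
    }) |>
    ungroup()
}

#' Log-rank test
#'
#' @param data A data frame.
#' @param time,event Column names of follow-up time and 0/1 event flag.
#' @param group Column name of the group labels (>= 2 groups).
#' @return A one-row tibble: `statistic` (log-rank chi-square), `df`,
#'   `p_value`, `n`, `n_groups`.
#' @export
logrank_test <- function(data, time, event, group) {
  stopifnot(is.data.frame(data))
  g <- data[[group]]
  if (length(unique(g[!is.na(g)])) < 2) abort("log-rank needs at least 2 groups")
  sd <- survival::survdiff(surv_formula(time, event, group), data = data)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
         n = sum(sd$n), n_groups = length(sd$n))
}

#' Pairwise log-rank tests between groups
#'
#' @inheritParams logrank_test
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `statistic`, `p_value`.
#' @export
pairwise_logrank <- function(data, time, event, group) {
  levels <- sort(unique(as.character(data[[group]][!is.na(data[[group]])])))
  if (length(levels) < 2) abort("log-rank needs at least 2 groups")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    sub <- data[data[[group]] %in% pr, , drop = FALSE]
    lr <- logrank_test(sub, time, event, group)
    tibble(group1 = pr[1], group2 = pr[2],
           statistic = lr$statistic, p_value = lr$p_value)
  }) |> list_rbind()
}

#' Log-rank-optimal cutoff for a continuous variable
#'
#' Scans every candidate cutoff (midpoints of consecutive sorted unique
#' values), discards candidates that would leave either group below
#' `min_group_fraction` of the sample, and returns the candidate maximizing
#' the log-rank chi-square, ties broken toward the smaller cutoff. The hazard
#' ratio of the dichotomized variable (high vs low group) is estimated by
#' univariate Cox regression. The p-value is the nominal log-rank p at the
#' selected cutoff and is not corrected for the maximal selection; treat it
#' as exploratory.
#'
#' @param data A data frame.
#' @param variable Column name of the continuous variable.
#' @param time,event Column names of follow-up time and 0/1 event flag.
#' @param min_group_fraction Minimum fraction of (complete-case) subjects on
#'   each side of an admissible cutoff (default 0.1).
#' @return A one-row tibble of class `cutoff_result`: `variable`, `cutoff`,
#'   `logrank_chi2`, `p_value`, `hr`, `ci_low`, `ci_high`, `n_low`, `n_high`,
#'   `n_used`.
#' @export
find_optimal_cutoff <- function(data, variable, time, event,
                                min_group_fraction = 0.1) {
  keep <- complete.cases(data[, c(variable, time, event)])
  d <- data[keep, , drop = FALSE]
  x <- d[[variable]]
  n <- length(x)
  ux <- sort(unique(x))
  if (length(ux) < 2) abort(sprintf("no admissible cutoff: '%s' is constant", variable))
  cand <- (head(ux, -1) + tail(ux, -1)) / 2
  floor_n <- min_group_fraction * n
  adm <- vapply(cand, function(ct) {
    nl <- sum(x <= ct)
    nl >= floor_n && (n - nl) >= floor_n
  }, logical(1))
  cand <- cand[adm]
  if (length(cand) == 0) {
    abort(sprintf("no admissible cutoff for '%s' at the %g%% group floor",
                  variable, 100 * min_group_fraction))
  }
  chi <- vapply(cand, function(ct) {
    d$.grp <- x > ct
    survival::survdiff(surv_formula(time, event, ".grp"), data = d)$chisq
  }, numeric(1))
  best <- cand[which.max(chi)]  # which.max takes the first = smallest cutoff on ties
  d$.grp <- as.integer(x > best)
  # HRs from extreme dichotomies can be unstable at small n (monotone
  # likelihood); the selection itself rests on the log-rank statistic
  cox <- suppressWarnings(
    survival::coxph(surv_formula(time, event, ".grp"), data = d,
                    ties = "efron"))
  ci <- suppressMessages(stats::confint(cox))
  lr <- logrank_test(d, time, event, ".grp")
  out <- tibble(
    variable = variable,
    cutoff = best,
    logrank_chi2 = max(chi),
    p_value = lr$p_value,
    hr = exp(unname(stats::coef(cox)[1])),
    ci_low = exp(ci[1, 1]),
    ci_high = exp(ci[1, 2]),
    n_low = sum(x <= best),
    n_high = sum(x > best),
    n_used = n
  )
  class(out) <- c("cutoff_result", class(out))
  out
}

#' Optimal-cutoff univariate screen over many variables
#'
#' Applies [find_optimal_cutoff()] to each variable for one endpoint,
#' collecting the dichotomized univariate results in one table. Variables
#' for which no admissible cutoff exists are skipped with a warning.
#'
#' @param data A data frame.
#' @param variables Character vector of continuous variable names.
#' @param time,event Column names of the endpoint.
#' @param min_group_fraction Group-size floor (see [find_optimal_cutoff()]).
#' @return A `cutoff_result` tibble with one row per variable.
#' @export
univariate_cutoff_screen <- function(data, variables, time, event,
                                     min_group_fraction = 0.1) {
  rows <- purrr::map(variables, function(v) {
    tryCatch(find_optimal_cutoff(data, v, time, event, min_group_fraction),
             error = function(e) {
               warn(sprintf("skipping '%s': %s", v, conditionMessage(e)))
               NULL
             })
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(variable = character(), cutoff = numeric(),
                  logrank_chi2 = numeric(), p_value = numeric(),
                  hr = numeric(), ci_low = numeric(), ci_high = numeric(),
                  n_low = integer(), n_high = integer(), n_used = integer())
  }
  class(out) <- c("cutoff_result", class(out))
  out
}

#' Dichotomize variables at given cutoffs
#'
#' @param data A data frame.
#' @param cutoffs A `cutoff_result` tibble (or any tibble with `variable` and
#'   `cutoff` columns).
#' @param suffix Appended to each variable name for the new 0/1 column
#'   (default `"_hi"`; 1 = value above the cutoff).
#' @return `data` with one additional 0/1 column per cutoff row.
#' @export
apply_cutoffs <- function(data, cutoffs, suffix = "_hi") {
  for (i in seq_len(nrow(cutoffs))) {
    v <- cutoffs$variable[i]
    data[[paste0(v, suffix)]] <- as.integer(data[[v]] > cutoffs$cutoff[i])
  }
  data
}
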