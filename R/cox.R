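# Cox proportional-hazards modeling: single fits (partial likelihood with
# Efron tie handling, via survival::coxph), forward/backward stepwise
# selection driven by likelihood-ratio tests, and leave-one-out
# cross-validated selection stability.

#' Fit a Cox proportional-hazards model
#'
#' Complete-case fit (rows with a missing value in any used column are
#' dropped; `n_used` reports the rows kept). Ties are handled with the Efron
#' approximation, appropriate for month-resolution follow-up times where tied
#' event times are guaranteed.
#'
#' @param data A data frame.
#' @param time,event Column names of follow-up time and 0/1 event flag.
#' @param variables Character vector of covariate names (may be empty: the
#'   null model).
#' @return An object of class `ig_cox`: a list with the underlying `coxph`
#'   fit (`NULL` for the null model), `variables`, `time`, `event`,
#'   `n_used`, `n_event`, `log_likelihood`, `null_log_likelihood`,
#'   `lr_statistic` (model vs null), `lr_df`, `lr_p_value`, `converged`.
#' @export
#' @examples
#' coh <- simulate_cohort(200, covariate_probs = c(arm = 0.5),
#'                        beta = c(arm = log(2)), seed = 3)
#' fit <- cox_fit(coh, "os_months", "os_event", "arm")
#' tidy(fit)
#' glance(fit)
cox_fit <- function(data, time, event, variables = character()) {
  stopifnot(is.data.frame(data))
  keep <- complete.cases(data[, c(variables, time, event), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (sum(d[[event]], na.rm = TRUE) < 1) abort("no events in the complete cases")
  if (length(variables) > 0) {
    novar <- variables[vapply(variables, function(v) {
      x <- d[[v]]
      length(unique(x[!is.na(x)])) < 2
    }, logical(1))]
    if (length(novar) > 0) {
      abort(sprintf("zero-variance covariate(s): %s", paste(novar, collapse = ", ")))
    }
  }
  if (length(variables) == 0) {
    fit0 <- survival::coxph(surv_formula(time, event, "1"), data = d)
    ll0 <- as.numeric(fit0$loglik[1])
    out <- list(fit = NULL, variables = character(), time = time, event = event,
                n_used = nrow(d), n_event = sum(d[[event]]),
                log_likelihood = ll0, null_log_likelihood = ll0,
                lr_statistic = 0, lr_df = 0L, lr_p_value = 1, converged = TRUE)
    class(out) <- "ig_cox"
    return(out)
  }
  rhs <- paste(sprintf("`%s`", variables), collapse = " + ")
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(surv_formula(time, event, rhs), data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  converged <- !warned && all(is.finite(beta)) &&
    all(is.finite(sqrt(diag(stats::vcov(fit)))))
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  out <- list(fit = fit, variables = variables, time = time, event = event,
              n_used = nrow(d), n_event = sum(d[[event]]),
              log_likelihood = as.numeric(fit$loglik[2]),
              null_log_likelihood = as.numeric(fit$loglik[1]),
              lr_statistic = as.numeric(lr), lr_df = length(beta),
              lr_p_value = pchisq(lr, length(beta), lower.tail = FALSE),
              converged = converged)
  class(out) <- "ig_cox"
  out
}

#' @export
print.ig_cox <- function(x, ...) {
  if (length(x$variables) == 0) {
    cat(sprintf("<ig_cox> null model, N = %d (%d events)\n", x$n_used, x$n_event))
  } else {
    cat(sprintf("<ig_cox> %s; LR %.2f (df %d, p %.3g), N = %d (%d events)%s\n",
                paste(x$variables, collapse = " + "),
                x$lr_statistic, x$lr_df, x$lr_p_value, x$n_used, x$n_event,
                if (x$converged) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}

#' @rdname cox_fit
#' @param x An `ig_cox` object.
#' @param ... Unused.
#' @method tidy ig_cox
#' @export
tidy.ig_cox <- function(x, ...) {
  if (length(x$variables) == 0) {
    return(tibble(term = character(), estimate = numeric(), hr = numeric(),
                  ci_low = numeric(), ci_high = numeric(),
                  wald_chi2 = numeric(), p_value = numeric()))
  }
  beta <- stats::coef(x$fit)
  se <- sqrt(diag(stats::vcov(x$fit)))
  z <- beta / se
  tibble(
    term = gsub("`", "", names(beta)),
    estimate = unname(beta),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta - qnorm(0.975) * se)),
    ci_high = exp(unname(beta + qnorm(0.975) * se)),
    wald_chi2 = unname(z^2),
    p_value = pchisq(unname(z^2), 1, lower.tail = FALSE)
  )
}

#' @rdname cox_fit
#' @method glance ig_cox
#' @export
glance.ig_cox <- function(x, ...) {
  tibble(n_used = x$n_used, n_event = x$n_event,
         log_likelihood = x$log_likelihood,
         null_log_likelihood = x$null_log_likelihood,
         lr_statistic = x$lr_statistic, lr_df = x$lr_df,
         lr_p_value = x$lr_p_value, converged = x$converged)
}

loglik_of <- function(data, time, event, variables) {
  if (length(variables) == 0) {
    fit0 <- survival::coxph(surv_formula(time, event, "1"), data = data)
    return(as.numeric(fit0$loglik[1]))
  }
  rhs <- paste(sprintf("`%s`", variables), collapse = " + ")
  fit <- suppressWarnings(
    survival::coxph(surv_formula(time, event, rhs), data = data, ties = "efron"))
  as.numeric(fit$loglik[2])
}

#' Stepwise Cox model selection by likelihood-ratio tests
#'
#' Forward selection with a likelihood-ratio entry test (add the candidate
#' with the largest entry LR among those with `p < alpha_enter`), followed
#' after every addition by backward LR removal checks (drop the variable with
#' the weakest contribution while its removal `p > alpha_remove`). Selection
#' runs on the complete cases of the full candidate set so that all LR
#' comparisons share one dataset; the returned model is refit on the complete
#' cases of the selected variables only, so its `n_used` reflects the final
#' variable set. Candidates that are constant (or that break the fit) on the
#' selection dataset are skipped. The procedure is deterministic.
#'
#' @param data A data frame.
#' @param time,event Column names of follow-up time and 0/1 event flag.
#' @param candidates Character vector of candidate covariate names.
#' @param alpha_enter LR entry threshold (default 0.05).
#' @param alpha_remove LR removal threshold (default 0.10).
#' @return An `ig_cox` model (the null model when nothing enters) with extra
#'   elements `selected`, `candidates` and `steps` (a tibble logging each
#'   add/remove with its LR statistic and p-value).
#' @export
stepwise_cox <- function(data, time, event, candidates,
                         alpha_enter = 0.05, alpha_remove = 0.10) {
  keep <- complete.cases(data[, c(candidates, time, event), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 2 || sum(d[[event]]) < 1) abort("not enough complete cases with events")
  usable <- candidates[vapply(candidates, function(v)
    length(unique(d[[v]])) > 1, logical(1))]
  current <- character()
  ll_current <- loglik_of(d, time, event, current)
  steps <- list()
  repeat {
    pool <- setdiff(usable, current)
    if (length(pool) == 0) break
    entry <- purrr::map(pool, function(v) {
      ll <- tryCatch(loglik_of(d, time, event, c(current, v)),
                     error = function(e) NA_real_)
      if (is.na(ll)) return(NULL)
      lr <- 2 * (ll - ll_current)
      tibble(variable = v, lr = lr, p = pchisq(lr, 1, lower.tail = FALSE), ll = ll)
    }) |> purrr::compact() |> list_rbind()
    if (nrow(entry) == 0) break
    entry <- entry |> filter(.data$p < alpha_enter) |> arrange(desc(.data$lr))
    if (nrow(entry) == 0) break
    current <- c(current, entry$variable[1])
    ll_current <- entry$ll[1]
    steps[[length(steps) + 1]] <- tibble(
      action = "add", variable = entry$variable[1],
      lr = entry$lr[1], p = entry$p[1])
    # backward pass
    repeat {
      if (length(current) < 2) break
      removal <- purrr::map(current, function(v) {
        ll <- loglik_of(d, time, event, setdiff(current, v))
        lr <- 2 * (ll_current - ll)
        tibble(variable = v, lr = lr, p = pchisq(lr, 1, lower.tail = FALSE), ll = ll)
      }) |> list_rbind()
      worst <- removal |> arrange(.data$lr) |> slice(1)
      if (worst$p <= alpha_remove) break
      current <- setdiff(current, worst$variable)
      ll_current <- worst$ll
      steps[[length(steps) + 1]] <- tibble(
        action = "remove", variable = worst$variable,
        lr = worst$lr, p = worst$p)
    }
  }
  model <- cox_fit(data, time, event, current)
  model$selected <- current
  model$candidates <- candidates
  model$steps <- list_rbind(steps) %||%
    tibble(action = character(), variable = character(),
           lr = numeric(), p = numeric())
  model
}

#' Leave-one-out stability of stepwise Cox selection
#'
#' Repeats [stepwise_cox()] on each of the `n` leave-one-out subsamples and
#' reports the selection frequency of every candidate. The final variable set
#' comprises the candidates selected in at least `freq_threshold` of the
#' folds; the final model is a full-data [cox_fit()] on that set.
#'
#' @inheritParams stepwise_cox
#' @param freq_threshold Minimum selection frequency for the final set
#'   (default 0.5).
#' @return An object of class `stability_report`: list with `frequencies`
#'   (tibble of candidate, n_selected, frequency), `final_set`,
#'   `final_model` (`ig_cox` or `NULL` when the final set is empty),
#'   `n_folds`, `n_failed`.
#' @export
loocv_stability <- function(data, time, event, candidates,
                            alpha_enter = 0.05, alpha_remove = 0.10,
                            freq_threshold = 0.5) {
  n <- nrow(data)
  if (n < 10) abort("leave-one-out stability needs at least 10 subjects")
  tallies <- setNames(rep(0L, length(candidates)), candidates)
  failed <- 0L
  for (i in seq_len(n)) {
    sel <- tryCatch(
      stepwise_cox(data[-i, , drop = FALSE], time, event, candidates,
                   alpha_enter, alpha_remove)$selected,
      error = function(e) NA
    )
    if (length(sel) == 1 && is.na(sel[1])) {
      failed <- failed + 1L
    } else if (length(sel) > 0) {
      tallies[sel] <- tallies[sel] + 1L
    }
  }
  ok <- n - failed
  freq <- tibble(
    variable = candidates,
    n_selected = as.integer(tallies),
    frequency = if (ok > 0) as.numeric(tallies) / ok else NA_real_
  )
  final_set <- freq$variable[!is.na(freq$frequency) & freq$frequency >= freq_threshold]
  final_model <- if (length(final_set) > 0) {
    cox_fit(data, time, event, final_set)
  } else NULL
  structure(
    list(frequencies = freq, final_set = final_set, final_model = final_model,
         n_folds = n, n_failed = failed, freq_threshold = freq_threshold),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d leave-one-out folds (%d failed)\n",
              x$n_folds, x$n_failed))
  print(x$frequencies)
  cat("final set:", if (length(x$final_set)) paste(x$final_set, collapse = ", ")
      else "(empty)", "\n")
  invisible(x)
}

#' @rdname loocv_stability
#' @param x A `stability_report`.
#' @param ... Unused.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$frequencies

#' @rdname loocv_stability
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble(n_folds = x$n_folds, n_failed = x$n_failed,
         n_final = length(x$final_set),
         freq_threshold = x$freq_threshold)
}
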