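# Cohort simulator: covariates plus survival endpoints from a Weibull
# proportional-hazards model with independent exponential censoring. Used for
# parameter-recovery and calibration testing of the survival stack.

#' Simulate a patient cohort from a Weibull proportional-hazards model
#'
#' Continuous covariates (e.g. log-scale density indicators) are drawn as
#' independent normals; binary covariates as Bernoulli. Event times follow
#' `h(t|x) = h0(t) * exp(beta' x)` with a Weibull baseline
#' `S0(t) = exp(-(t/scale)^shape)`. Censoring times are independent
#' exponentials whose rate is calibrated so the expected censoring fraction
#' equals `censoring_rate`. Overall-survival and recurrence-free-survival
#' endpoints are drawn independently from the same model (RFS optionally with
#' its own coefficient vector).
#'
#' @param n_patients Number of patients (>= 2).
#' @param covariate_means,covariate_sds Named numeric vectors defining the
#'   continuous (log-scale) covariates.
#' @param covariate_probs Named numeric vector of Bernoulli probabilities for
#'   binary covariates.
#' @param beta Named numeric vector of log hazard ratios for overall
#'   survival; names must be a subset of the generated covariates.
#' @param beta_rfs Log hazard ratios for the recurrence endpoint
#'   (default: same as `beta`).
#' @param baseline_shape,baseline_scale Weibull baseline parameters
#'   (scale in months).
#' @param censoring_rate Target expected fraction of censored observations in
#'   `[0, 1]`.
#' @param round_months Round observed times up to whole months (creates the
#'   tied event times typical of month-resolution follow-up; default FALSE).
#' @param covariates Optional data frame of pre-computed covariates (e.g.
#'   measured indicator values); overrides the covariate generation and sets
#'   the cohort size to its row count.
#' @param seed Integer seed.
#' @return A tibble with `patient_id`, one column per covariate, and
#'   `os_months`, `os_event`, `rfs_months`, `rfs_event`.
#' @export
#' @examples
#' coh <- simulate_cohort(50, covariate_probs = c(arm = 0.5),
#'                        beta = c(arm = log(2)), seed = 1)
simulate_cohort <- function(n_patients,
                            covariate_means = NULL,
                            covariate_sds = NULL,
                            covariate_probs = NULL,
                            beta = NULL,
                            beta_rfs = beta,
                            baseline_shape = 1.2,
                            baseline_scale = 60,
                            censoring_rate = 0.4,
                            round_months = FALSE,
                            covariates = NULL,
                            seed = NULL) {
  if (!is.null(covariates)) n_patients <- nrow(covariates)
  if (n_patients < 2) abort("`n_patients` must be >= 2.")
  if (censoring_rate < 0 || censoring_rate > 1) {
    abort("`censoring_rate` must be in [0, 1].")
  }
  if (!is.null(covariate_means)) {
    if (is.null(covariate_sds)) covariate_sds <- rep(1, length(covariate_means))
    if (is.null(names(covariate_means))) abort("`covariate_means` must be named.")
    covariate_sds <- rep_len(covariate_sds, length(covariate_means))
  }
  with_seed(seed, {
    if (is.null(covariates)) {
      covs <- list()
      if (!is.null(covariate_means)) {
        for (i in seq_along(covariate_means)) {
          covs[[names(covariate_means)[i]]] <-
            rnorm(n_patients, covariate_means[[i]], covariate_sds[[i]])
        }
      }
      if (!is.null(covariate_probs)) {
        for (nm in names(covariate_probs)) {
          covs[[nm]] <- rbinom(n_patients, 1, covariate_probs[[nm]])
        }
      }
      covs <- as_tibble(covs)
    } else {
      covs <- as_tibble(covariates)
    }
    if (ncol(covs) == 0) covs <- tibble(.rows = n_patients)
    draw_endpoint <- function(b) {
      lp <- rep(0, n_patients)
      if (!is.null(b) && length(b) > 0) {
        missing_cov <- setdiff(names(b), names(covs))
        if (length(missing_cov) > 0) {
          abort(sprintf("`beta` names not among covariates: %s",
                        paste(missing_cov, collapse = ", ")))
        }
        lp <- as.numeric(as.matrix(covs[, names(b), drop = FALSE]) %*% b)
      }
      t_event <- baseline_scale * (-log(runif(n_patients)) / exp(lp))^(1 / baseline_shape)
      if (censoring_rate >= 1) {
        time <- t_event * runif(n_patients)
        event <- rep(0L, n_patients)
      } else if (censoring_rate <= 0) {
        time <- t_event
        event <- rep(1L, n_patients)
      } else {
        # P(censored) = 1 - E[exp(-r T)]; solve for the exponential rate r on
        # the realized event times (deterministic given the draw)
        f <- function(logr) 1 - mean(exp(-exp(logr) * t_event)) - censoring_rate
        logr <- uniroot(f, c(-20, 20), extendInt = "yes")$root
        t_cens <- rexp(n_patients, exp(logr))
        time <- pmin(t_event, t_cens)
        event <- as.integer(t_event <= t_cens)
      }
      if (round_months) time <- pmax(1, ceiling(time))
      list(time = time, event = event)
    }
    os <- draw_endpoint(beta)
    rfs <- draw_endpoint(beta_rfs)
    ids <- if ("patient_id" %in% names(covs)) {
      pid <- covs$patient_id
      covs <- select(covs, -"patient_id")
      pid
    } else sprintf("P%03d", seq_len(n_patients))
    bind_cols(
      tibble(patient_id = ids),
      covs,
      tibble(os_months = os$time, os_event = os$event,
             rfs_months = rfs$time, rfs_event = rfs$event)
    )
  })
}
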