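test_that("Cox coefficients match direct maximization of the Efron partial likelihood", {
  # 8-subject fixture with tied event times
  d <- tibble::tibble(
    t = c(4, 4, 6, 8, 8, 10, 12, 12),
    e = c(1, 1, 1, 0, 1, 1, 1, 0),
    x1 = c(0, 1, 1, 0, 1, 0, 1, 0),
    x2 = c(1.2, -0.5, 0.3, 2.0, -1.0, 0.7, 0.1, -0.3)
  )
  fit <- cox_fit(d, "t", "e", c("x1", "x2"))
  opt <- optim(c(0, 0),
               function(b) -oracle_efron_loglik(b, d[, c("x1", "x2")], d$t, d$e),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(coef(fit$fit)), opt$par, tolerance = 1e-6)
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-8)
})

test_that("a known log hazard ratio is recovered at n = 1000", {
  coh <- simulate_cohort(1000, covariate_probs = c(g = 0.5),
                         beta = c(g = log(2)), censoring_rate = 0.3,
                         seed = 71)
  fit <- cox_fit(coh, "os_months", "os_event", "g")
  expect_lt(abs(tidy(fit)$estimate - log(2)), 0.15)
  expect_equal(glance(fit)$n_used, 1000)
})

test_that("degenerate inputs are refused or flagged", {
  d <- tibble::tibble(t = rexp(20, 0.1), e = 1, x = 1)
  expect_error(cox_fit(d, "t", "e", "x"), "zero-variance")

  # monotone likelihood (perfect separation) is flagged, not silent
  ds <- tibble::tibble(t = c(1, 2, 3, 4, 10, 11, 12, 13),
                       e = 1, x = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- cox_fit(ds, "t", "e", "x")
  expect_false(fit$converged)
})

test_that("complete-case handling drives the per-model N", {
  set.seed(81)
  d <- simulate_cohort(60, covariate_means = c(a = 0, b = 0), seed = 82)
  d$a[1:10] <- NA
  fit_a <- cox_fit(d, "os_months", "os_event", "a")
  fit_b <- cox_fit(d, "os_months", "os_event", "b")
  expect_equal(fit_a$n_used, 50)
  expect_equal(fit_b$n_used, 60)
})

test_that("stepwise selection keeps a strong predictor among noise", {
  set.seed(91)
  hit <- replicate(20, {
    n <- 400
    covs <- tibble::tibble(sig = rbinom(n, 1, 0.5))
    for (k in 1:9) covs[[paste0("z", k)]] <- rnorm(n)
    coh <- simulate_cohort(covariates = covs, beta = c(sig = log(3)),
                           censoring_rate = 0.25, seed = sample.int(2^30, 1))
    sel <- stepwise_cox(coh, "os_months", "os_event",
                        c("sig", paste0("z", 1:9)))$selected
    "sig" %in% sel
  })
  expect_gte(mean(hit), 0.9)
})

test_that("stepwise with no candidates or no signal returns the null model", {
  coh <- simulate_cohort(60, covariate_means = c(z = 0), seed = 95)
  m0 <- stepwise_cox(coh, "os_months", "os_event", character())
  expect_length(m0$variables, 0)
  expect_equal(m0$lr_statistic, 0)
})

test_that("leave-one-out stability reports frequencies in [0, 1]", {
  set.seed(97)
  covs <- tibble::tibble(strong = rbinom(80, 1, 0.5),
                         z1 = rnorm(80), z2 = rnorm(80))
  coh <- simulate_cohort(covariates = covs, beta = c(strong = 1.6),
                         censoring_rate = 0.2, seed = 98)
  rep <- loocv_stability(coh, "os_months", "os_event",
                         c("strong", "z1", "z2"))
  expect_true(all(rep$frequencies$frequency >= 0 &
                    rep$frequencies$frequency <= 1))
  expect_equal(rep$frequencies$frequency[rep$frequencies$variable == "strong"], 1)
  expect_true("strong" %in% rep$final_set)
  expect_s3_class(rep$final_model, "ig_cox")
  expect_error(loocv_stability(coh[1:5, ], "os_months", "os_event", "strong"),
               "at least 10")
})
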