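test_that("tissue simulation is deterministic and matches disc geometry", {
  tm1 <- simulate_tissue_map(2000, 2000, pixel_size_um = 4, n_blobs = 1,
                             blob_radius_um = 500, seed = 11)
  tm2 <- simulate_tissue_map(2000, 2000, pixel_size_um = 4, n_blobs = 1,
                             blob_radius_um = 500, seed = 11)
  expect_identical(tm1$labels, tm2$labels)

  # exactly one connected epithelial component (4-neighbour flood fill)
  comp <- EBImage::bwlabel(tm1$labels == 1L)
  expect_equal(max(comp), 1)

  # epithelium pixel fraction vs closed-form circle area, within 2%
  frac <- mean(tm1$labels == 1L)
  expect_equal(frac, pi * 500^2 / (2000 * 2000), tolerance = 0.02)

  expect_error(simulate_tissue_map(800, 800, n_blobs = 1, blob_radius_um = 450),
               "blob diameter")
})

test_that("cell placement follows the configured Poisson intensities", {
  # constant intensity 100/mm^2 over 1 mm^2 of pure stroma
  tm <- tissue_map(matrix(2L, 250, 250), pixel_size_um = 4)
  tm$labels[1, 1] <- 1L  # a single epithelial pixel to define the interface
  lam <- c(stroma_far = 100, stroma_near = 100, edge = 100,
           epi_near = 100, epi_far = 100)
  cells <- simulate_cells(tm, lambda = lam, band_width_um = 50,
                          background_negative_lambda = 0, seed = 21)
  expect_lt(abs(sum(cells$cd8_positive) - 100), 40)

  # all-zero intensities -> no cells, not an error
  none <- simulate_cells(tm, lambda = lam * 0, background_negative_lambda = 0,
                         seed = 1)
  expect_equal(nrow(none), 0)

  # no cells on background pixels
  tmb <- simulate_tissue_map(1500, 1500, pixel_size_um = 4, n_blobs = 1,
                             blob_radius_um = 300, background_border_um = 100,
                             seed = 3)
  cb <- simulate_cells(tmb, seed = 4)
  ix <- cbind(ceiling(cb$y_um / 4), ceiling(cb$x_um / 4))
  expect_true(all(tmb$labels[ix] != 0L))
})

test_that("band intensities recover a 4:1 stroma-to-epithelium ratio", {
  tm <- simulate_tissue_map(4000, 4000, pixel_size_um = 4, n_blobs = 6,
                            blob_radius_um = 400, seed = 31)
  cells <- simulate_cells(
    tm, lambda = c(stroma_far = 200, stroma_near = 200, edge = 100,
                   epi_near = 50, epi_far = 50),
    band_width_um = 100, background_negative_lambda = 0, seed = 32)
  sd_um <- signed_interface_distance(tm)
  pos <- cells[cells$cd8_positive, ]
  d_cell <- sd_um[cbind(ceiling(pos$y_um / 4), ceiling(pos$x_um / 4))]
  px2 <- 16
  dens_near_s <- sum(d_cell >= -150 & d_cell < -50) /
    (sum(sd_um >= -150 & sd_um < -50) * px2 / 1e6)
  dens_near_e <- sum(d_cell > 50 & d_cell <= 150) /
    (sum(sd_um > 50 & sd_um <= 150) * px2 / 1e6)
  expect_equal(dens_near_s / dens_near_e, 4, tolerance = 0.25)
})

test_that("cohort simulation honours the proportional-hazards model", {
  expect_error(simulate_cohort(1), ">= 2")

  # censoring fraction within binomial error of the target
  coh <- simulate_cohort(600, censoring_rate = 0.3, seed = 41)
  p_hat <- mean(coh$os_event == 0)
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 600))

  # full censoring -> no events at all
  cc <- simulate_cohort(50, censoring_rate = 1, seed = 42)
  expect_true(all(cc$os_event == 0) && all(cc$rfs_event == 0))
  expect_true(all(cc$os_months > 0))

  # beta keys must name generated covariates
  expect_error(simulate_cohort(20, beta = c(nope = 1), seed = 1),
               "not among covariates")

  # determinism
  a <- simulate_cohort(30, covariate_probs = c(arm = 0.5), seed = 7)
  b <- simulate_cohort(30, covariate_probs = c(arm = 0.5), seed = 7)
  expect_identical(a, b)
})

test_that("baseline survival matches the closed-form Weibull survivor function", {
  coh <- simulate_cohort(2000, censoring_rate = 0, baseline_shape = 1.2,
                         baseline_scale = 60, seed = 51)
  km <- kaplan_meier(coh, "os_months", "os_event")
  s_true <- exp(-(km$time / 60)^1.2)
  expect_lt(max(abs(km$survival - s_true)), 0.05)
})

test_that("null log-rank p-values are uniform across simulated cohorts", {
  set.seed(61)
  pvals <- replicate(200, {
    coh <- simulate_cohort(40, covariate_probs = c(g = 0.5), beta = NULL,
                           censoring_rate = 0.2,
                           seed = sample.int(2^30, 1))
    logrank_test(coh, "os_months", "os_event", "g")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
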