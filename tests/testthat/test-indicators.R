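# a minimal interface-zone tibble with chosen per-compartment densities
zone_fixture <- function(dens_s, dens_te, dens_t, region = "malignant") {
  n_s <- length(dens_s); n_te <- length(dens_te); n_t <- length(dens_t)
  tibble::tibble(
    q = seq_len(n_s + n_te + n_t), r = 0L,
    compartment = rep(c("S", "TE", "T"), c(n_s, n_te, n_t)),
    position = rep(c(1, 2, 3), c(n_s, n_te, n_t)),
    rank = rep(c(-2L, 0L, 2L), c(n_s, n_te, n_t)),
    cd8_density_mm2 = c(dens_s, dens_te, dens_t),
    region_label = region
  )
}

test_that("compartment statistics use the sample standard deviation", {
  st <- compartment_stats(zone_fixture(10, c(20, 30), c(40, 60)))
  expect_equal(st$m[st$compartment == "T"], 50)
  expect_equal(st$sd[st$compartment == "T"], sd(c(40, 60)))
  expect_equal(round(st$sd[st$compartment == "T"], 3), 14.142)
  # single-hexagon compartment has sd 0, not NA
  expect_equal(st$sd[st$compartment == "S"], 0)
  expect_error(compartment_stats(zone_fixture(numeric(), 1, 1)),
               "compartment S is empty")
})

test_that("center of mass hits its closed forms", {
  expect_equal(center_of_mass(c(100, 100, 100)), 2)
  expect_equal(center_of_mass(c(0, 0, 100)), 3)
  expect_equal(center_of_mass(c(200, 100, 50)), 550 / 350)
  expect_equal(round(center_of_mass(c(200, 100, 50)), 4), 1.5714)
  expect_true(is.na(center_of_mass(c(0, 0, 0))))
  expect_error(center_of_mass(c(-1, 1, 1)), "non-negative")
})

test_that("immunodrop is the stromal-to-epithelial density ratio", {
  expect_equal(immunodrop(200, 50), 4)
  expect_equal(immunodrop(80, 80), 1)
  expect_true(is.na(immunodrop(100, 0)))
})

test_that("log transform uses natural log with a pseudo-count for zeros", {
  ind <- tibble::tibble(m_T = c(105, 0), sd_T = c(0, 2), ID = c(1, 4),
                        CM_m = c(2, 2))
  lg <- log_transform_indicators(ind)
  expect_equal(round(lg$m_T[1], 3), 4.654)
  expect_equal(lg$m_T[2], 0)
  expect_equal(lg$sd_T[1], 0)
  expect_equal(lg$ID, c(0, log(4)))
  expect_equal(lg$CM_m, log(c(2, 2)))
})

test_that("indicators are invariant to hexagon order and scale correctly", {
  z <- zone_fixture(c(120, 80, 100), c(60, 70), c(20, 30, 25))
  ind <- compute_indicators(z)
  set.seed(4)
  perm <- z[sample(nrow(z)), ]
  expect_equal(compute_indicators(perm), ind)

  # scaling all densities by c > 0: m and sd scale, CM and ID unchanged
  z2 <- z
  z2$cd8_density_mm2 <- z2$cd8_density_mm2 * 3.7
  ind2 <- compute_indicators(z2)
  for (col in c("m_S", "m_TE", "m_T", "sd_S", "sd_TE", "sd_T")) {
    expect_equal(ind2[[col]], ind[[col]] * 3.7)
  }
  expect_equal(ind2$CM_m, ind$CM_m)
  expect_equal(ind2$CM_sd, ind$CM_sd)
  expect_equal(ind2$ID, ind$ID)
})

test_that("a stroma-to-epithelium gradient is recovered from one slide", {
  ind <- gradient_slide_indicators(715)
  expect_equal(ind$m_S / ind$m_T, 4, tolerance = 0.25)
  expect_lt(ind$CM_m, 2)
  expect_gt(ind$ID, 1)
})

test_that("indicator tables pivot to the prefixed reporting layout", {
  rows <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), each = 2),
    region_label = rep(c("malignant", "non_malignant"), 2),
    m_T = c(1, 2, 3, 4), sd_TE = c(5, 6, 7, 8), ID = c(1, 1, 2, 2)
  )
  w <- indicator_wide(rows)
  expect_setequal(names(w), c("patient_id", "HCC_m_T", "Liver_m_T",
                              "HCC_sd_TE", "Liver_sd_TE", "HCC_ID", "Liver_ID"))
  expect_equal(w$HCC_m_T, c(1, 3))
  expect_equal(w$Liver_sd_TE, c(6, 8))
})
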