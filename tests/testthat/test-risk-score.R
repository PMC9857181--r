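five_rules <- risk_rules(paste0("v", 1:5), cutoff = rep(0.5, 5),
                         poor_when = "above")

test_that("score sums rule contributions over all 32 combinations", {
  combos <- expand.grid(rep(list(0:1), 5))
  names(combos) <- paste0("v", 1:5)
  sc <- assign_risk_score(tibble::as_tibble(combos), five_rules)
  expect_equal(sc$score, rowSums(combos))
  expected_cat <- ifelse(sc$score <= 1, "low",
                         ifelse(sc$score == 2, "intermediate", "high"))
  expect_equal(as.character(sc$category), expected_cat)
  # boundary cases of the documented mapping
  expect_equal(as.character(sc$category[sc$score == 5][1]), "high")
  expect_equal(as.character(sc$category[sc$score == 0][1]), "low")
})

test_that("score is monotone: flipping any rule to poor never decreases it", {
  combos <- expand.grid(rep(list(0:1), 5))
  names(combos) <- paste0("v", 1:5)
  sc <- assign_risk_score(tibble::as_tibble(combos), five_rules)$score
  for (k in 1:5) {
    low <- combos[[paste0("v", k)]] == 0
    flipped <- combos
    flipped[[paste0("v", k)]] <- 1L
    sc_flip <- assign_risk_score(tibble::as_tibble(flipped), five_rules)$score
    expect_true(all(sc_flip[low] >= sc[low]))
  }
})

test_that("rule direction follows the hazard-ratio sign of the source model", {
  coh <- simulate_cohort(400, covariate_probs = c(good = 0.5, bad = 0.5),
                         beta = c(good = -1, bad = 1), censoring_rate = 0.2,
                         seed = 111)
  coh$good_hi <- coh$good
  coh$bad_hi <- coh$bad
  fit <- cox_fit(coh, "os_months", "os_event", c("good_hi", "bad_hi"))
  cutoffs <- tibble::tibble(variable = c("good", "bad"), cutoff = c(0.5, 0.5))
  rules <- rules_from_model(fit, cutoffs)
  expect_equal(rules$poor_when[rules$variable == "bad"], "above")
  expect_equal(rules$poor_when[rules$variable == "good"], "below")
})

test_that("the two-rule immune score maps 0/1/2 to the three tiers", {
  rules2 <- risk_rules(c("hcc_sd", "liver_m"), c(5.7, 4.7),
                       poor_when = c("below", "above"))
  d <- tibble::tibble(patient_id = c("A", "B", "C"),
                      hcc_sd = c(6.0, 6.0, 5.0),
                      liver_m = c(4.0, 5.0, 5.0))
  sc <- cd8_risk_score(d, rules2)
  expect_equal(sc$score, c(0, 1, 2))
  expect_equal(as.character(sc$category), c("low", "intermediate", "high"))
  expect_error(cd8_risk_score(d, five_rules), "exactly two")
})

test_that("patients missing a rule variable are excluded with a message", {
  d <- tibble::tibble(patient_id = c("A", "B"),
                      v1 = c(1, NA), v2 = 1, v3 = 0, v4 = 0, v5 = 0)
  expect_message(sc <- assign_risk_score(d, five_rules), "excluded")
  expect_true(is.na(sc$score[2]))
  expect_false(sc$scored[2])
  expect_equal(sc$score[1], 2)
})

test_that("stratified survival needs at least two populated tiers", {
  coh <- simulate_cohort(40, seed = 121)
  coh$category <- factor("low", levels = c("low", "intermediate", "high"))
  expect_error(stratified_survival(coh, "os_months", "os_event"),
               "at least 2")
  # two identical tiers (duplicated data) cannot be separated
  dup <- dplyr::bind_rows(
    dplyr::mutate(coh, category = factor("low")),
    dplyr::mutate(coh, category = factor("high")))
  st <- stratified_survival(dup, "os_months", "os_event")
  expect_equal(st$pairwise$p_value, 1, tolerance = 1e-8)
})
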