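test_that("same config and seed reproduce identical tables", {
  cfg <- synth_config(n_practices = 8, mean_patients_per_practice = 25,
                      seed = 77)
  a <- generate_ehr(cfg)
  b <- generate_ehr(cfg)
  for (tab in c("patients", "visits", "prescriptions", "ground_truth"))
    expect_identical(a[[tab]], b[[tab]])
  expect_identical(a$true_ate, b$true_ate)
})

test_that("without confounding the telemedicine share matches the intercept", {
  p0 <- 0.3
  cfg <- synth_config(n_practices = 50, mean_patients_per_practice = 100,
                      propensity_intercept = qlogis(p0),
                      propensity_coefficients = list(),
                      practice_intercept_sd = 0,
                      missingness_rates = numeric(0),
                      repeat_visit_probability = 0, seed = 101)
  ehr <- generate_ehr(cfg)
  gt <- ehr$ground_truth
  expect_true(all(abs(gt$true_propensity - p0) < 1e-12))
  v <- ehr$visits[match(gt$visit_id, ehr$visits$visit_id), ]
  share <- mean(flag_exposure(v) == "telemedicine")
  se <- sqrt(p0 * (1 - p0) / nrow(gt))
  expect_lt(abs(share - p0), 3 * se)
})

test_that("a zero effect knob with modality-independent mechanisms gives an exactly null truth", {
  cfg <- recovery_config(seed = 5, n_practices = 20,
                         mean_patients_per_practice = 30)
  cfg$true_ate_knob <- 0
  validate_cfg <- generate_ehr(cfg)
  expect_identical(validate_cfg$true_ate, 0)
  expect_identical(validate_cfg$ground_truth$y_tele,
                   validate_cfg$ground_truth$y_inperson)
})

test_that("empirical covariate marginals converge to the configured ones", {
  cfg <- synth_config(n_practices = 250, mean_patients_per_practice = 200,
                      missingness_rates = numeric(0), seed = 2024)
  pat <- generate_ehr(cfg)$patients
  n <- nrow(pat)
  expect_gt(n, 45000)
  for (cov in c("race_ethnicity", "census_division", "payer")) {
    probs <- cfg$covariate_marginals[[cov]]
    for (lv in names(probs)) {
      p <- probs[[lv]]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(pat[[cov]] == lv) - p), 3 * se)
    }
  }
})

test_that("true propensities are calibrated against realized assignment", {
  ehr <- generate_ehr(recovery_config(seed = 31, n_practices = 150,
                                      mean_patients_per_practice = 100))
  gt <- ehr$ground_truth
  v <- ehr$visits[match(gt$visit_id, ehr$visits$visit_id), ]
  z <- flag_exposure(v) == "telemedicine"
  bins <- cut(gt$true_propensity,
              stats::quantile(gt$true_propensity, seq(0, 1, 0.2)),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    p <- mean(gt$true_propensity[sel])
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(z[sel]) - p), 4 * se)
  }
})

test_that("invalid configuration errors name the offending key", {
  expect_error(synth_config(concordant_drug_probability = 1.4),
               "concordant_drug_probability")
  expect_error(synth_config(covariate_marginals = modifyList(
    default_marginals(), list(payer = c(medicaid = 0.6, other = 0.6)))),
    "payer")
  expect_error(synth_config(n_practices = 0), "n_practices")
  expect_error(synth_config(practice_intercept_sd = -1),
               "practice_intercept_sd")
})

test_that("missingness injection hits its rate and validates fields", {
  pat <- generate_ehr(synth_config(n_practices = 40,
                                   mean_patients_per_practice = 250,
                                   missingness_rates = numeric(0),
                                   seed = 9))$patients
  expect_identical(inject_missingness(pat, c(payer = 0), seed = 1), pat)
  all_na <- inject_missingness(pat, c(payer = 1), seed = 1)
  expect_true(all(is.na(all_na$payer)))
  r <- 0.119
  sub <- pat[seq_len(10000), ]
  out <- inject_missingness(sub, c(census_division = r), seed = 2)
  se <- sqrt(r * (1 - r) / 10000)
  expect_lt(abs(mean(is.na(out$census_division)) - r), 3 * se)
  expect_error(inject_missingness(pat, c(no_such_field = 0.1)),
               "no_such_field")
  expect_error(inject_missingness(pat, c(payer = 1.2)), "\\[0, 1\\]")
})

test_that("complete-case exclusion matches the union missingness probability", {
  r <- 0.0615
  cfg <- synth_config(n_practices = 60, mean_patients_per_practice = 170,
                      missingness_rates = c(race_ethnicity = r,
                                            census_division = r),
                      excluded_dx_rate = 0, well_visit_rate = 0,
                      codx_rate = 0, seed = 88)
  ehr <- generate_ehr(cfg)
  cohort <- build_episodes(ehr$patients, ehr$visits, ehr$prescriptions,
                           code_registry())
  cc <- complete_case_filter(cohort$episodes)
  p_union <- 1 - (1 - r)^2  # inclusion-exclusion with independent blanking
  n <- nrow(cohort$episodes)
  expect_lt(abs(cc$excluded_fraction - p_union),
            3 * sqrt(p_union * (1 - p_union) / n))
})
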