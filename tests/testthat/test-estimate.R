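test_that("Hajek arm means reduce to simple percentages and are scale-invariant", {
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  z <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(weighted_arm_means(y, z, rep(1, 8)),
               c(inperson = 40, telemedicine = 200 / 3))
  w <- c(2, 1, 1, 3, 1, 1, 2, 1)
  base <- weighted_arm_means(y, z, w)
  w2 <- ifelse(z == 1, 2 * w, w)  # doubling one arm's weights changes nothing
  expect_equal(weighted_arm_means(y, z, w2), base)
  # hand-computed ratio for the weighted toy table
  expect_equal(base[["telemedicine"]], 100 * (2 + 1) / 4)
  expect_equal(base[["inperson"]], 100 * (3 + 2) / 8)
  expect_error(weighted_arm_means(y, rep(1, 8), w), "nonempty")
})

test_that("cluster-robust SE matches an independent M-estimation sandwich", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 30
    y <- rbinom(n, 1, 0.5)
    z <- rbinom(n, 1, 0.4)
    if (length(unique(z)) < 2) next
    w <- runif(n, 0.5, 4)
    g <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    fit <- arti_ate(y, z, w, g)
    orc <- oracle_sandwich(y, z, w, g)
    expect_equal(fit$ate, orc$est, tolerance = 1e-10)
    expect_equal(fit$se_robust, orc$se, tolerance = 1e-10)
    expect_equal(unname(fit$arm_se[c("telemedicine", "inperson")]),
                 orc$arm_se, tolerance = 1e-10)
    # self-consistency: effect = difference of the reported arm percentages
    expect_equal(fit$ate, fit$weighted_pct[["telemedicine"]] -
                   fit$weighted_pct[["inperson"]], tolerance = 1e-12)
    expect_equal(fit$ci95, fit$ate + c(-1, 1) * qnorm(0.975) * fit$se_robust)
  }
})

test_that("degenerate estimation inputs error explicitly", {
  y <- rbinom(20, 1, 0.5)
  z <- rep(c(0, 1), 10)
  expect_error(arti_ate(y, z, rep(1, 20), rep("only", 20)), "single cluster")
  expect_equal(arti_ate(y, z, rep(1, 20), rep(c("a", "b"), 10))$ate,
               100 * (mean(y[z == 1]) - mean(y[z == 0])))
})

test_that("identical arms give a zero effect", {
  y <- rep(c(1, 0), 20)
  z <- rep(c(1, 0), each = 20)
  g <- rep(c("a", "b", "c", "d"), 10)
  fit <- arti_ate(y, z, rep(1, 40), g)
  expect_equal(fit$ate, 0)
})

test_that("subgroup analysis recovers level-specific effects", {
  set.seed(32)
  n <- 12000
  lvl <- sample(c("low", "high"), n, replace = TRUE)
  x <- rbinom(n, 1, 0.5)
  e <- plogis(-1 + 1.5 * x)
  z <- rbinom(n, 1, e)
  eff <- ifelse(lvl == "low", -0.20, 0)
  p <- plogis(-0.3 + 1.0 * x) + eff * z
  y <- rbinom(n, 1, pmin(pmax(p, 0), 1))
  ep <- data.frame(
    modality = ifelse(z == 1, "telemedicine", "inperson"),
    x = x, lvl = lvl, y = y,
    practice_id = sample(sprintf("P%02d", 1:30), n, replace = TRUE),
    stringsAsFactors = FALSE)
  sg <- subgroup_analysis(ep, "lvl", "y",
                          propensity_spec(covariates = c("x", "lvl"),
                                          interactions = character(0),
                                          engine = "fixed"))
  expect_identical(sort(sg$level), c("high", "low"))
  lo <- sg[sg$level == "low", ]
  hi <- sg[sg$level == "high", ]
  expect_lt(abs(lo$ate - (-20)), 3 * lo$se)
  expect_lt(abs(hi$ate - 0), 3 * hi$se)
  # a constant subgroup variable reproduces the main analysis without it
  ep1 <- ep[ep$lvl == "low", ]
  sg1 <- subgroup_analysis(ep1, "lvl", "y",
                           propensity_spec(covariates = c("x", "lvl"),
                                           interactions = character(0),
                                           engine = "fixed"))
  main <- teleabx:::refit_and_estimate(
    ep1, "y", propensity_spec(covariates = "x",
                              interactions = character(0),
                              engine = "fixed"), "ATE")
  expect_equal(sg1$ate, main$ate)
  expect_equal(sg1$se, main$se_robust)
})

test_that("single-arm subgroup levels are skipped with a warning", {
  ep <- data.frame(
    modality = c(rep("inperson", 10), rep(c("inperson", "telemedicine"), 5)),
    x = rbinom(20, 1, 0.5),
    lvl = rep(c("solo", "both"), each = 10),
    y = rbinom(20, 1, 0.5),
    practice_id = rep(c("P1", "P2"), 10),
    stringsAsFactors = FALSE)
  expect_warning(
    sg <- subgroup_analysis(ep, "lvl", "y",
                            propensity_spec(covariates = "x",
                                            interactions = character(0),
                                            engine = "fixed")),
    "single exposure arm")
  expect_identical(sg$level, "both")
})

test_that("diagnosis-conditional analysis honours the viral identity", {
  res <- run_arti_pipeline(recovery_config(seed = 62, n_practices = 50,
                                           mean_patients_per_practice = 60),
                           spec = propensity_spec(engine = "fixed"))
  dc <- diagnosis_conditional(res$episodes, "viral_arti",
                              propensity_spec(engine = "fixed"))
  # for viral episodes concordance is exactly "no antibiotic": the weighted
  # concordance percentage is 100 minus the antibiotic percentage, per arm
  expect_equal(dc$concordant$weighted_pct[["inperson"]],
               100 - dc$prescribed_antibiotic$weighted_pct[["inperson"]],
               tolerance = 1e-9)
  expect_equal(dc$concordant$weighted_pct[["telemedicine"]],
               100 - dc$prescribed_antibiotic$weighted_pct[["telemedicine"]],
               tolerance = 1e-9)
  expect_equal(dc$concordant$ate, -dc$prescribed_antibiotic$ate,
               tolerance = 1e-9)
  expect_error(diagnosis_conditional(res$episodes, "no_such_label"),
               "no episodes")
})

test_that("suppressed telemedicine prescribing for strep lowers both outcomes", {
  cfg <- recovery_config(seed = 63, n_practices = 60,
                         mean_patients_per_practice = 80)
  dxp <- c(strep_pharyngitis = 1, acute_otitis_media = 0,
           bacterial_sinusitis = 0, viral_arti = 0)
  cfg$diagnosis_probabilities <- list(inperson = dxp, telemedicine = dxp)
  cfg$true_ate_knob <- -0.30
  ehr <- generate_ehr(cfg)
  res <- run_arti_pipeline(ehr, spec = propensity_spec(engine = "fixed"))
  dc <- diagnosis_conditional(res$episodes, "strep_pharyngitis",
                              propensity_spec(engine = "fixed"))
  # fewer antibiotics for strep means less concordant strep care
  expect_lt(dc$prescribed_antibiotic$ate, 0)
  expect_lt(dc$concordant$ate, 0)
})

test_that("weighted diagnosis shares per arm sum to 100", {
  res <- run_arti_pipeline(recovery_config(seed = 64, n_practices = 40,
                                           mean_patients_per_practice = 50),
                           spec = propensity_spec(engine = "fixed"))
  mix <- res$diagnosis_mix
  four <- mix[mix$diagnosis %in% dx_labels(), ]
  expect_equal(sum(four$pct_inperson), 100, tolerance = 1e-9)
  expect_equal(sum(four$pct_telemedicine), 100, tolerance = 1e-9)
  bact <- mix[mix$diagnosis == "bacterial", ]
  expect_equal(bact$pct_inperson,
               sum(four$pct_inperson[four$diagnosis != "viral_arti"]),
               tolerance = 1e-9)
  # toy cross-check against a brute-force weighted tabulation
  set.seed(65)
  ep <- res$episodes[sample(nrow(res$episodes), 200), ]
  z <- ep$modality == "telemedicine"
  w <- runif(200, 0.5, 2)
  mix2 <- diagnosis_mix(ep, z, w, ep$practice_id)
  lab <- mix2$diagnosis[1]
  expect_equal(mix2$pct_inperson[1],
               100 * sum(w[!z] * (ep$diagnosis[!z] == lab)) / sum(w[!z]))
})
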