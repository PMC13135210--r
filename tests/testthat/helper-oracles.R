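## Independent brute-force oracles and shared fixtures. These deliberately
## re-derive results from first principles (pairwise window predicates,
## explicit M-estimation algebra) rather than reusing package internals.

## Generator configuration for estimator-property experiments: a single
## built-in risk-difference effect of -12 percentage points, strong
## confounding (pre-weighting covariate ASBs around 0.5), a ~14%
## telemedicine share so reduced-size replicates keep a usable treated arm,
## propensities bounded away from 0/1 (positivity: coefficient magnitudes
## <= 1.5, so IPTW's balancing behaviour is observable rather than drowned
## by extreme-weight noise), and none of the exclusion/missingness noise
## channels, so the bookkept truth refers to the analysis sample itself.
recovery_config <- function(seed, n_practices = 100,
                            mean_patients_per_practice = 100) {
  dxp <- c(strep_pharyngitis = 0.132, acute_otitis_media = 0.263,
           bacterial_sinusitis = 0.049, viral_arti = 0.556)
  synth_config(
    n_practices = n_practices,
    mean_patients_per_practice = mean_patients_per_practice,
    propensity_intercept = -2.9,
    propensity_coefficients = list(
      age_group = c(">=12" = 0.3),
      race_ethnicity = c(Hispanic = 1.3, Other = 0.5),
      census_division = c(mountain = 1.4, pacific = 1.5),
      season = c(winter = 0.4),
      clinician_specialty = c(family_medicine = 1.4),
      medical_complexity_flag = 0.3,
      prior_telemedicine = 1.5,
      prior_antibiotics = -0.8,
      prior_well_visits = -0.3),
    practice_intercept_sd = 0.3,
    diagnosis_probabilities = list(inperson = dxp, telemedicine = dxp),
    true_ate_knob = -0.12,
    missingness_rates = numeric(0),
    excluded_dx_rate = 0, well_visit_rate = 0, codx_rate = 0,
    repeat_visit_probability = 0, topical_rx_rate = 0,
    seed = seed)
}

## the propensity specification matching the recovery generator exactly
## (no season x region interaction; the generator has none)
recovery_spec <- function() {
  propensity_spec(engine = "fixed", interactions = character(0))
}

## lean replicate: generate -> episodes -> fixed-engine IPTW -> ATE,
## skipping the balance diagnostics (used in replicated experiments)
recovery_replicate <- function(seed, n_practices, mean_patients,
                               outcome = "prescribed_antibiotic") {
  ehr <- generate_ehr(recovery_config(seed, n_practices, mean_patients))
  cohort <- build_episodes(ehr$patients, ehr$visits, ehr$prescriptions,
                           code_registry())
  ep <- attach_outcomes(cohort$episodes, code_registry())
  fit <- fit_propensity(ep, recovery_spec())
  z <- ep$modality == "telemedicine"
  wts <- compute_weights(predict(fit), z, "ATE")
  est <- arti_ate(ep[[outcome]], z, wts$w, ep$practice_id)
  naive <- 100 * (mean(ep[[outcome]][z]) - mean(ep[[outcome]][!z]))
  list(est = est, naive = naive, truth = ehr$true_ate, episodes = ep,
       weights = wts)
}

## brute-force episode construction: for every ARTI visit of one patient,
## check the 21-day lookback against *all* other visits, then anchor
## followups/orphans to the most recent index by exhaustive search
oracle_episode_status <- function(day, id, lookback = 21, fwindow = 14) {
  ord <- order(day, id)
  day <- day[ord]; id <- id[ord]
  n <- length(day)
  status <- character(n)
  anchor <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    blocked <- FALSE
    for (j in seq_len(n)) {
      if (j != i && day[j] >= day[i] - lookback && day[j] <= day[i] - 1)
        blocked <- TRUE
      if (j != i && day[j] == day[i] && id[j] < id[i]) blocked <- TRUE
    }
    if (!blocked) { status[i] <- "index"; anchor[i] <- i; next }
    best <- NA_integer_
    for (j in seq_len(n)) {
      if (status[j] == "index" &&
          (day[j] < day[i] || (day[j] == day[i] && id[j] < id[i])) &&
          day[i] - day[j] <= fwindow) {
        if (is.na(best) || day[j] > day[best]) best <- j
      }
    }
    if (!is.na(best)) { status[i] <- "followup"; anchor[i] <- best }
    else status[i] <- "orphan"
  }
  data.frame(visit_id = id, day = day, status = status,
             anchor_id = ifelse(is.na(anchor), NA_character_, id[anchor]),
             stringsAsFactors = FALSE)
}

## independent cluster-robust sandwich for the difference of two Hajek
## ratio means, via stacked estimating equations A^{-1} B A^{-T}
oracle_sandwich <- function(y, Z, w, g) {
  Z <- as.numeric(Z)
  mu_t <- sum(w * Z * y) / sum(w * Z)
  mu_c <- sum(w * (1 - Z) * y) / sum(w * (1 - Z))
  A <- diag(c(sum(w * Z), sum(w * (1 - Z))))
  psi <- cbind(w * Z * (y - mu_t), w * (1 - Z) * (y - mu_c))
  S <- rowsum(psi, as.character(g))
  B <- t(S) %*% S
  V <- solve(A) %*% B %*% t(solve(A))
  cvec <- c(1, -1)
  list(est = 100 * (mu_t - mu_c),
       se = 100 * sqrt(drop(t(cvec) %*% V %*% cvec)),
       arm_se = 100 * sqrt(diag(V)))
}

## rule-table oracle for guideline concordance, written as a literal
## enumeration of the published rule set
oracle_concordance <- function(label, drugs) {
  drugs <- tolower(drugs)
  has_abx <- length(drugs) > 0
  ok <- switch(label,
    strep_pharyngitis = has_abx &&
      all(drugs %in% c("amoxicillin", "penicillin")),
    acute_otitis_media = ,
    bacterial_sinusitis = !has_abx ||
      all(drugs %in% c("amoxicillin", "amoxicillin-clavulanic acid")),
    viral_arti = !has_abx)
  ok
}

## printed covariate margins of the worked example: unweighted arm counts
## for every binary covariate level, with the published standardized bias
## and the decimal places it was printed at
example_margins <- function() {
  n_ip <- 438148; n_te <- 11482
  rows <- rbind(
    data.frame(level = "age_lt12",      ip = 369524, te = 9085, asb = -0.14, dp = 2),
    data.frame(level = "age_ge12",      ip = 68624,  te = 2397, asb = 0.14,  dp = 2),
    data.frame(level = "spring",        ip = 103532, te = 2464, asb = -0.05, dp = 2),
    data.frame(level = "summer",        ip = 68401,  te = 1597, asb = -0.05, dp = 2),
    data.frame(level = "fall",          ip = 135078, te = 3041, asb = -0.1,  dp = 1),
    data.frame(level = "winter",        ip = 131137, te = 4380, asb = 0.17,  dp = 2),
    data.frame(level = "northeast",     ip = 258396, te = 1653, asb = -1.04, dp = 2),
    data.frame(level = "midwest",       ip = 41641,  te = 1178, asb = 0.03,  dp = 2),
    data.frame(level = "south",         ip = 68021,  te = 1000, asb = -0.21, dp = 2),
    data.frame(level = "west",          ip = 70090,  te = 7651, asb = 1.2,   dp = 1),
    data.frame(level = "hispanic",      ip = 91592,  te = 6618, asb = 0.81,  dp = 2),
    data.frame(level = "white",         ip = 278083, te = 2398, asb = -0.96, dp = 2),
    data.frame(level = "other_race",    ip = 25195,  te = 1313, asb = 0.2,   dp = 1),
    data.frame(level = "complexity",    ip = 59329,  te = 1976, asb = 0.1,   dp = 1),
    data.frame(level = "pediatrics",    ip = 369138, te = 4284, asb = -1.1,  dp = 1),
    data.frame(level = "family_med",    ip = 69010,  te = 7198, asb = 1.1,   dp = 1),
    data.frame(level = "any_well",      ip = 199925, te = 3596, asb = -0.3,  dp = 1),
    data.frame(level = "any_problem",   ip = 249546, te = 6414, asb = -0.02, dp = 2),
    data.frame(level = "any_tele",      ip = 17231,  te = 3699, asb = 0.79,  dp = 2),
    data.frame(level = "any_abx",       ip = 103288, te = 922,  asb = -0.44, dp = 2))
  rows$p_ip <- rows$ip / n_ip
  rows$p_te <- rows$te / n_te
  rows
}

## small deterministic visit/prescription tables for cohort unit tests
toy_tables <- function() {
  visits <- data.frame(
    visit_id = sprintf("V%02d", 1:6),
    patient_id = c("A", "A", "A", "B", "B", "C"),
    practice_id = "P1",
    day = c(10, 13, 24, 40, 40, 100),
    visit_type = "problem",
    diagnosis_codes = c("ARTI-V1", "ARTI-V2", "ARTI-S1", "ARTI-O1",
                        "ARTI-V1", "ARTI-N1"),
    billing_modifier = c("", "", "95", "", "", ""),
    place_of_service = "11",
    video_flag = 0L,
    clinician_specialty = "pediatrics",
    stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    practice_id = "P1",
    age_years = c(4, 13, 8),
    race_ethnicity = c("White", "Hispanic", "Black"),
    census_division = c("pacific", "new_england", "mountain"),
    payer = "medicaid", language = "english", rurality = "urban",
    medical_complexity_flag = 0L,
    prior_well_visits = 1L, prior_problem_visits = 0L,
    prior_telemedicine = 0L, prior_antibiotics = 0L,
    stringsAsFactors = FALSE)
  prescriptions <- data.frame(
    rx_id = sprintf("R%02d", 1:4),
    patient_id = c("A", "A", "B", "C"),
    day = c(10, 13, 41, 101),
    drug_name = c("amoxicillin", "azithromycin", "amoxicillin", "mupirocin"),
    systemic_flag = c(1L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
  list(patients = patients, visits = visits, prescriptions = prescriptions)
}
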