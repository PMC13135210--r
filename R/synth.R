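#' Configuration for the synthetic EHR generator
#'
#' Describes the generative mechanism the analysis assumes: practices with a
#' random intercept on telemedicine uptake, children with categorical
#' demographic and prior-utilization covariates, presenting ARTI visits whose
#' modality follows a logistic propensity model, diagnoses drawn conditional
#' on modality (emulating modality-driven diagnosis shifting), antibiotic
#' prescribing conditional on diagnosis, modality and covariates, and
#' follow-up visit dynamics in the 0-2, 3-10 and 11-14 day windows.
#'
#' Both potential prescribing outcomes (under telemedicine and under
#' in-person care) are generated for every presenting visit before one is
#' revealed, so the true average treatment effect of the generated cohort is
#' known exactly, not estimated.
#'
#' `true_ate_knob` is declared on the risk-difference scale: the telemedicine
#' prescribing probability equals the in-person probability for the same
#' child and diagnosis plus the knob (clamped to \[0, 1\]). A knob of -0.12
#' therefore builds in a treatment effect of about -12 percentage points.
#' `true_ate_knob_by_dx` optionally overrides the knob per diagnosis label.
#'
#' Default marginals approximate a large US pediatric primary-care cohort:
#' 84% of visits by children under 12, 16% family-medicine clinics, and a
#' telemedicine share near 2.5%. They are deliberately approximate fixtures.
#'
#' @param n_practices number of practices (>= 1).
#' @param mean_patients_per_practice Poisson mean of the practice panel size.
#' @param practice_intercept_sd standard deviation (log-odds scale) of the
#'   practice random intercept on telemedicine use. The practice-level
#'   variance of telemedicine uptake is a free parameter of the generator.
#' @param covariate_marginals named list of category-probability vectors, one
#'   per patient covariate; each must sum to 1.
#' @param propensity_intercept log-odds intercept of telemedicine assignment.
#' @param propensity_coefficients named list: covariate -> log-odds effects on
#'   telemedicine (named vector per category, or a single number for a 0/1
#'   covariate).
#' @param outcome_coefficients same structure, log-odds effects on antibiotic
#'   prescribing; these shared causes of modality and prescribing are what
#'   create confounding.
#' @param diagnosis_probabilities list with elements `inperson` and
#'   `telemedicine`, each a probability vector over the four diagnosis labels.
#' @param prescribing_probabilities list with elements `inperson` and
#'   `telemedicine`: baseline antibiotic probability per diagnosis label.
#' @param concordant_drug_probability probability that a prescribed drug is
#'   first-line for the (bacterial) diagnosis.
#' @param followup_hazards list with elements `inperson` and `telemedicine`,
#'   each `c(w0_2 =, w3_10 =, w11_14 =)`: probability of a follow-up ARTI
#'   visit in each day window after a presenting visit.
#' @param followup_abx_probability probability a follow-up visit in the 3-10
#'   or 11-14 day window carries a systemic antibiotic prescription.
#' @param true_ate_knob built-in modality effect on prescribing
#'   (risk-difference scale; see Details).
#' @param true_ate_knob_by_dx optional named numeric overriding the knob for
#'   specific diagnosis labels.
#' @param missingness_rates named numeric: fraction of each patient covariate
#'   set missing by [inject_missingness()].
#' @param excluded_dx_rate,well_visit_rate,codx_rate rates at which presenting
#'   visits are seeded with an excluded diagnosis code, a well-child visit
#'   type, or an antibiotic-warranting codiagnosis (exercises the exclusion
#'   filters).
#' @param repeat_visit_probability probability a child has a second,
#'   independent presenting visit later in the year.
#' @param topical_rx_rate rate of non-systemic (topical) noise prescriptions.
#' @param seed integer seed; all sub-streams are derived from it.
#' @return An object of class `synth_config`.
#' @seealso [generate_ehr()]
#' @export
synth_config <- function(n_practices = 50,
                         mean_patients_per_practice = 60,
                         practice_intercept_sd = 0.4,
                         covariate_marginals = default_marginals(),
                         propensity_intercept = -6.3,
                         propensity_coefficients = default_propensity_coefs(),
                         outcome_coefficients = default_outcome_coefs(),
                         diagnosis_probabilities = list(
                           inperson = c(strep_pharyngitis = 0.132,
                                        acute_otitis_media = 0.263,
                                        bacterial_sinusitis = 0.049,
                                        viral_arti = 0.556),
                           telemedicine = c(strep_pharyngitis = 0.073,
                                            acute_otitis_media = 0.110,
                                            bacterial_sinusitis = 0.147,
                                            viral_arti = 0.670)),
                         prescribing_probabilities = list(
                           inperson = c(strep_pharyngitis = 0.90,
                                        acute_otitis_media = 0.68,
                                        bacterial_sinusitis = 0.85,
                                        viral_arti = 0.20),
                           telemedicine = c(strep_pharyngitis = 0.90,
                                            acute_otitis_media = 0.68,
                                            bacterial_sinusitis = 0.85,
                                            viral_arti = 0.20)),
                         concordant_drug_probability = 0.85,
                         followup_hazards = list(
                           inperson = c(w0_2 = 0.014, w3_10 = 0.049,
                                        w11_14 = 0.028),
                           telemedicine = c(w0_2 = 0.058, w3_10 = 0.069,
                                            w11_14 = 0.022)),
                         followup_abx_probability = 0.35,
                         true_ate_knob = -0.07,
                         true_ate_knob_by_dx = NULL,
                         missingness_rates = c(race_ethnicity = 0.0615,
                                               census_division = 0.0615),
                         excluded_dx_rate = 0.03,
                         well_visit_rate = 0.02,
                         codx_rate = 0.02,
                         repeat_visit_probability = 0.15,
                         topical_rx_rate = 0.01,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' @rdname synth_config
#' @export
default_marginals <- function() {
  list(
    age_group = c("<12" = 0.84, ">=12" = 0.16),
    race_ethnicity = c(Black = 0.10, Hispanic = 0.21,
                       White = 0.63, Other = 0.06),
    census_division = c(new_england = 0.20, middle_atlantic = 0.39,
                        east_north_central = 0.055,
                        west_north_central = 0.04,
                        south_atlantic = 0.08, east_south_central = 0.035,
                        west_south_central = 0.04,
                        mountain = 0.06, pacific = 0.10),
    payer = c(medicaid = 0.55, other = 0.40, uninsured = 0.05),
    language = c(english = 0.80, spanish = 0.15, other = 0.05),
    rurality = c(urban = 0.80, micropolitan = 0.12, small_town_rural = 0.08),
    medical_complexity_flag = c("0" = 0.865, "1" = 0.135),
    prior_well_visits = c("0" = 0.55, "1" = 0.45),
    prior_problem_visits = c("0" = 0.43, "1" = 0.57),
    prior_telemedicine = c("0" = 0.955, "1" = 0.045),
    prior_antibiotics = c("0" = 0.77, "1" = 0.23)
  )
}

#' @rdname synth_config
#' @export
default_propensity_coefs <- function() {
  list(
    age_group = c(">=12" = 0.35),
    race_ethnicity = c(Hispanic = 1.6, Other = 0.7),
    census_division = c(mountain = 2.2, pacific = 2.4),
    season = c(winter = 0.45),
    clinician_specialty = c(family_medicine = 2.2),
    medical_complexity_flag = 0.3,
    prior_telemedicine = 2.4,
    prior_antibiotics = -1.3,
    prior_well_visits = -0.5
  )
}

#' @rdname synth_config
#' @export
default_outcome_coefs <- function() {
  list(
    age_group = c(">=12" = -0.4),
    race_ethnicity = c(Hispanic = -0.3),
    census_division = c(mountain = -0.5, pacific = -0.6),
    season = c(winter = 0.4),
    medical_complexity_flag = 0.5,
    prior_antibiotics = 0.9
  )
}

validate_synth_config <- function(cfg) {
  chk01 <- function(x, key) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop("invalid probability in '", key, "': values must lie in [0, 1]")
  }
  if (cfg$n_practices < 1) stop("n_practices must be >= 1")
  if (cfg$practice_intercept_sd < 0)
    stop("practice_intercept_sd must be >= 0")
  for (nm in names(cfg$covariate_marginals)) {
    p <- cfg$covariate_marginals[[nm]]
    chk01(p, paste0("covariate_marginals$", nm))
    if (abs(sum(p) - 1) > 1e-8)
      stop("category probabilities for covariate '", nm,
           "' must sum to 1 (got ", format(sum(p)), ")")
  }
  for (side in c("inperson", "telemedicine")) {
    dp <- cfg$diagnosis_probabilities[[side]]
    chk01(dp, paste0("diagnosis_probabilities$", side))
    if (abs(sum(dp) - 1) > 1e-8)
      stop("diagnosis_probabilities$", side, " must sum to 1")
    if (!setequal(names(dp), dx_labels()))
      stop("diagnosis_probabilities$", side,
           " must name the four diagnosis labels")
    chk01(cfg$prescribing_probabilities[[side]],
          paste0("prescribing_probabilities$", side))
    chk01(cfg$followup_hazards[[side]],
          paste0("followup_hazards$", side))
  }
  chk01(cfg$concordant_drug_probability, "concordant_drug_probability")
  chk01(cfg$followup_abx_probability, "followup_abx_probability")
  chk01(cfg$missingness_rates, "missingness_rates")
  for (r in c("excluded_dx_rate", "well_visit_rate", "codx_rate",
              "repeat_visit_probability", "topical_rx_rate"))
    chk01(cfg[[r]], r)
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [synth_config()].
#' @return A `synth_config` object.
#' @export
read_synth_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  listify <- function(x) if (is.list(x)) lapply(x, unlist) else x
  for (nm in c("covariate_marginals", "propensity_coefficients",
               "outcome_coefficients", "diagnosis_probabilities",
               "prescribing_probabilities", "followup_hazards"))
    if (!is.null(y[[nm]])) y[[nm]] <- listify(y[[nm]])
  if (!is.null(y$missingness_rates))
    y$missingness_rates <- unlist(y$missingness_rates)
  do.call(synth_config, y)
}

## season by day-of-year quartile: integer day offsets in one study year
season_of_day <- function(day) {
  cut(((day - 1L) %% 365L) + 1L, breaks = c(0, 91, 182, 273, 365),
      labels = c("winter", "spring", "summer", "fall"))
}

## census division -> 4-region collapse used for presentation and the
## season x region propensity interaction
division_to_region <- function(division) {
  map <- c(new_england = "Northeast", middle_atlantic = "Northeast",
           east_north_central = "Midwest", west_north_central = "Midwest",
           south_atlantic = "South", east_south_central = "South",
           west_south_central = "South",
           mountain = "West", pacific = "West")
  unname(map[as.character(division)])
}

## additive log-odds contribution of covariate columns; `coefs` entries are
## either a named vector over categories or a single number for 0/1 columns
lin_pred <- function(df, coefs) {
  lp <- numeric(nrow(df))
  for (nm in names(coefs)) {
    if (!nm %in% names(df))
      stop("coefficient refers to unknown covariate: ", nm)
    co <- coefs[[nm]]
    if (is.null(names(co)) && length(co) == 1L) {
      lp <- lp + co * as.numeric(as.character(df[[nm]]))
    } else {
      add <- unname(co[match(as.character(df[[nm]]), names(co))])
      add[is.na(add)] <- 0
      lp <- lp + add
    }
  }
  lp
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate synthetic EHR tables with known ground truth
#'
#' Draws practices, patients, presenting ARTI visits, follow-up visits and
#' prescriptions under the mechanism described in [synth_config()]. Modality
#' is assigned by `logit(e) = intercept + beta'x + b_practice`; the diagnosis
#' is drawn conditional on modality; the antibiotic outcome conditional on
#' diagnosis, modality and covariates. Potential outcomes under both
#' modalities are generated from one shared uniform draw (coupling), so with
#' a zero effect knob and modality-independent diagnosis and prescribing
#' mechanisms the two potential outcomes are identical and the true effect is
#' exactly zero.
#'
#' @param config a [synth_config()] object.
#' @return A list with components `patients`, `visits`, `prescriptions`
#'   (data frames matching the package CSV schemas), `ground_truth` (one row
#'   per presenting visit: `visit_id`, `y_tele`, `y_inperson`,
#'   `true_propensity`) and `true_ate` (mean potential-outcome difference in
#'   percentage points), plus the `config` used.
#' @examples
#' ehr <- generate_ehr(synth_config(n_practices = 5,
#'                                  mean_patients_per_practice = 20,
#'                                  seed = 42))
#' head(ehr$visits)
#' ehr$true_ate
#' @export
generate_ehr <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  m <- cfg$covariate_marginals

  ## --- practices ---------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  n_prac <- as.integer(cfg$n_practices)
  practices <- data.frame(
    practice_id = sprintf("P%04d", seq_len(n_prac)),
    b_practice = stats::rnorm(n_prac, 0, cfg$practice_intercept_sd),
    clinician_specialty = sample_cat(
      n_prac, c(pediatrics = 0.84, family_medicine = 0.16)),
    stringsAsFactors = FALSE)

  ## --- patients ----------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  n_per <- pmax(1L, stats::rpois(n_prac, cfg$mean_patients_per_practice))
  n_pat <- sum(n_per)
  pat_prac <- rep(practices$practice_id, n_per)
  age_group <- sample_cat(n_pat, m$age_group)
  age_years <- ifelse(age_group == "<12",
                      round(stats::runif(n_pat, 0, 11.99), 1),
                      round(stats::runif(n_pat, 12, 17.99), 1))
  patients <- data.frame(
    patient_id = sprintf("C%06d", seq_len(n_pat)),
    practice_id = pat_prac,
    age_years = age_years,
    race_ethnicity = sample_cat(n_pat, m$race_ethnicity),
    census_division = sample_cat(n_pat, m$census_division),
    payer = sample_cat(n_pat, m$payer),
    language = sample_cat(n_pat, m$language),
    rurality = sample_cat(n_pat, m$rurality),
    medical_complexity_flag = as.integer(
      sample_cat(n_pat, m$medical_complexity_flag)),
    prior_well_visits = as.integer(sample_cat(n_pat, m$prior_well_visits)),
    prior_problem_visits = as.integer(
      sample_cat(n_pat, m$prior_problem_visits)),
    prior_telemedicine = as.integer(sample_cat(n_pat, m$prior_telemedicine)),
    prior_antibiotics = as.integer(sample_cat(n_pat, m$prior_antibiotics)),
    stringsAsFactors = FALSE)

  ## --- presenting visits -------------------------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  repeat_flag <- stats::rbinom(n_pat, 1L, cfg$repeat_visit_probability) == 1L
  idx1 <- seq_len(n_pat)
  idx <- c(idx1, idx1[repeat_flag])
  day1 <- sample.int(365L, n_pat, replace = TRUE)
  ## second presenting visit at least 36 days later: clears both the 21-day
  ## index lookback and the 14-day follow-up window of the first episode
  day <- c(day1, day1[repeat_flag] +
             sample(36:120, sum(repeat_flag), replace = TRUE))
  pv <- patients[idx, , drop = FALSE]
  pv$day <- day
  pv$season <- as.character(season_of_day(pv$day))
  pv$age_group <- age_group[idx]
  pv$clinician_specialty <- practices$clinician_specialty[
    match(pv$practice_id, practices$practice_id)]
  b_p <- practices$b_practice[match(pv$practice_id, practices$practice_id)]
  n_v <- nrow(pv)

  e_true <- stats::plogis(cfg$propensity_intercept +
                            lin_pred(pv, cfg$propensity_coefficients) + b_p)
  z <- stats::runif(n_v) < e_true
  modality <- ifelse(z, "telemedicine", "inperson")

  ## coupled diagnosis draw under each modality (shared uniform)
  labs <- dx_labels()
  u_dx <- stats::runif(n_v)
  pick_dx <- function(side) {
    p <- cfg$diagnosis_probabilities[[side]][labs]
    labs[pmin(findInterval(u_dx, cumsum(p), left.open = TRUE) + 1L,
              length(labs))]
  }
  dx_ip <- pick_dx("inperson")
  dx_te <- pick_dx("telemedicine")

  ## coupled potential prescribing outcomes
  gamma <- lin_pred(pv, cfg$outcome_coefficients)
  knob <- rep(cfg$true_ate_knob, n_v)
  if (!is.null(cfg$true_ate_knob_by_dx)) {
    ov <- cfg$true_ate_knob_by_dx[dx_te]
    knob <- ifelse(is.na(ov), knob, ov)
  }
  p_ip <- stats::plogis(
    stats::qlogis(unname(cfg$prescribing_probabilities$inperson[dx_ip])) +
      gamma)
  p_te <- clamp(stats::plogis(
    stats::qlogis(unname(cfg$prescribing_probabilities$telemedicine[dx_te])) +
      gamma) + knob, 0, 1)
  u_y <- stats::runif(n_v)
  y_ip <- as.integer(u_y < p_ip)
  y_te <- as.integer(u_y < p_te)
  y <- ifelse(z, y_te, y_ip)
  dx <- ifelse(z, dx_te, dx_ip)

  ## visit-level fields: diagnosis codes, exclusion noise, modality evidence
  set.seed(derive_seed(cfg$seed, 4L))
  reg <- code_registry()
  dx_sets <- list(strep_pharyngitis = reg$arti_strep,
                  acute_otitis_media = reg$arti_aom,
                  bacterial_sinusitis = reg$arti_sinusitis,
                  viral_arti = reg$arti_viral)
  pick_code <- function(sets_idx) {
    vapply(sets_idx, function(s) sample(dx_sets[[s]], 1L), "")
  }
  codes <- pick_code(dx)
  add_viral <- dx != "viral_arti" & stats::runif(n_v) < 0.15
  codes[add_viral] <- paste(codes[add_viral],
                            sample(reg$arti_viral, sum(add_viral),
                                   replace = TRUE), sep = "|")
  excl <- stats::runif(n_v) < cfg$excluded_dx_rate
  codes[excl] <- paste(codes[excl],
                       sample(reg$excluded_dx, sum(excl), replace = TRUE),
                       sep = "|")
  codx <- stats::runif(n_v) < cfg$codx_rate
  codes[codx] <- paste(codes[codx],
                       sample(reg$abx_warranting_codx, sum(codx),
                              replace = TRUE), sep = "|")
  visit_type <- ifelse(stats::runif(n_v) < cfg$well_visit_rate,
                       "well_child", "problem")

  ## telemedicine evidence: one of modifier GT/95, telehealth place of
  ## service, or a video flag (OR semantics downstream)
  pat_id <- sample.int(5L, n_v, replace = TRUE)
  modifier <- ifelse(z, c("GT", "95", "", "", "95")[pat_id], "")
  pos <- ifelse(z, c("11", "11", "02", "10", "10")[pat_id], "11")
  video <- as.integer(z & pat_id %in% c(4L, 5L))

  visits <- data.frame(
    visit_id = NA_character_,
    patient_id = pv$patient_id,
    practice_id = pv$practice_id,
    day = pv$day,
    visit_type = visit_type,
    diagnosis_codes = codes,
    billing_modifier = modifier,
    place_of_service = pos,
    video_flag = video,
    clinician_specialty = pv$clinician_specialty,
    stringsAsFactors = FALSE)

  ## --- follow-up visits and subsequent antibiotics ------------------------
  set.seed(derive_seed(cfg$seed, 5L))
  fu_rows <- list()
  fu_rx <- list()
  windows <- list(w0_2 = 1:2, w3_10 = 3:10, w11_14 = 11:14)
  for (w in names(windows)) {
    hz <- ifelse(z, cfg$followup_hazards$telemedicine[w],
                 cfg$followup_hazards$inperson[w])
    hit <- stats::runif(n_v) < hz
    if (!any(hit)) next
    off <- sample(windows[[w]], sum(hit), replace = TRUE)
    fu <- data.frame(
      visit_id = NA_character_,
      patient_id = pv$patient_id[hit],
      practice_id = pv$practice_id[hit],
      day = pv$day[hit] + off,
      visit_type = "problem",
      diagnosis_codes = sample(reg$arti_viral, sum(hit), replace = TRUE),
      billing_modifier = "",
      place_of_service = "11",
      video_flag = 0L,
      clinician_specialty = pv$clinician_specialty[hit],
      stringsAsFactors = FALSE)
    fu_rows[[w]] <- fu
    if (w %in% c("w3_10", "w11_14")) {
      gets_rx <- stats::runif(nrow(fu)) < cfg$followup_abx_probability
      if (any(gets_rx))
        fu_rx[[w]] <- data.frame(
          patient_id = fu$patient_id[gets_rx],
          day = fu$day[gets_rx],
          drug_name = sample(reg$systemic_antibiotics, sum(gets_rx),
                             replace = TRUE),
          systemic_flag = 1L,
          stringsAsFactors = FALSE)
    }
  }
  visits <- rbind(visits, do.call(rbind, fu_rows))
  visits$visit_id <- sprintf("V%07d", seq_len(nrow(visits)))

  ## --- prescriptions linked to presenting visits -------------------------
  set.seed(derive_seed(cfg$seed, 6L))
  got <- which(y == 1L)
  rx_day <- pv$day[got] + sample(0:2, length(got), replace = TRUE,
                                 prob = c(0.7, 0.2, 0.1))
  firstline_of <- function(d) reg$firstline[[d]]
  nonfirst <- function(d) setdiff(reg$systemic_antibiotics, reg$firstline[[d]])
  use_first <- stats::runif(length(got)) < cfg$concordant_drug_probability
  drug <- character(length(got))
  for (i in seq_along(got)) {
    d <- dx[got[i]]
    pool <- if (use_first[i] && length(firstline_of(d))) firstline_of(d)
            else nonfirst(d)
    drug[i] <- pool[sample.int(length(pool), 1L)]
  }
  rx_index <- data.frame(patient_id = pv$patient_id[got], day = rx_day,
                         drug_name = drug, systemic_flag = 1L,
                         stringsAsFactors = FALSE)
  topical <- which(stats::runif(n_v) < cfg$topical_rx_rate)
  rx_top <- data.frame(patient_id = pv$patient_id[topical],
                       day = pv$day[topical] + 1L,
                       drug_name = rep("mupirocin", length(topical)),
                       systemic_flag = rep(0L, length(topical)),
                       stringsAsFactors = FALSE)
  prescriptions <- rbind(rx_index, do.call(rbind, fu_rx), rx_top)
  if (is.null(prescriptions))
    prescriptions <- data.frame(patient_id = character(), day = integer(),
                                drug_name = character(),
                                systemic_flag = integer())
  prescriptions <- cbind(
    rx_id = sprintf("R%07d", seq_len(nrow(prescriptions))), prescriptions,
    stringsAsFactors = FALSE)
  rownames(prescriptions) <- NULL

  ## --- ground truth -------------------------------------------------------
  ground_truth <- data.frame(
    visit_id = visits$visit_id[seq_len(n_v)],
    y_tele = y_te, y_inperson = y_ip,
    true_propensity = e_true,
    stringsAsFactors = FALSE)

  ## --- missingness --------------------------------------------------------
  if (length(cfg$missingness_rates) && any(cfg$missingness_rates > 0))
    patients <- inject_missingness(patients, cfg$missingness_rates,
                                   seed = derive_seed(cfg$seed, 7L))

  list(patients = patients, visits = visits, prescriptions = prescriptions,
       ground_truth = ground_truth,
       true_ate = 100 * mean(y_te - y_ip),
       config = cfg)
}

#' Blank covariate fields at given rates
#'
#' Independently sets each targeted patient-table field to `NA` with its
#' rate, emulating EHR missingness (the complete-case filter downstream drops
#' episodes missing required covariates).
#'
#' @param patients patient table.
#' @param rates named numeric in `[0, 1]`; names must be patient columns.
#' @param seed optional integer seed for reproducibility.
#' @return The patient table with injected `NA`s.
#' @export
inject_missingness <- function(patients, rates, seed = NULL) {
  stopifnot(is.numeric(rates))
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  unknown <- setdiff(names(rates), names(patients))
  if (length(unknown))
    stop("unknown covariate in missingness rates: ",
         paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(rates)) {
    hit <- stats::runif(nrow(patients)) < rates[[nm]]
    patients[[nm]][hit] <- NA
  }
  patients
}

#' Write the generated tables as CSV files
#'
#' @param ehr result of [generate_ehr()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_ehr_csv <- function(ehr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(ehr$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(ehr$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  utils::write.csv(ehr$prescriptions, file.path(dir, "prescriptions.csv"),
                   row.names = FALSE)
  utils::write.csv(ehr$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
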