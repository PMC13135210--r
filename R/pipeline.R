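#' Run the full episode-construction and weighting analysis
#'
#' End-to-end convenience wrapper: (optionally) generate synthetic EHR
#' tables, build ARTI episodes, apply the exclusion and complete-case
#' filters, attach outcomes, fit the propensity model, construct weights,
#' compute balance diagnostics, and estimate the effect of telemedicine for
#' each requested outcome.
#'
#' @param ehr either a [synth_config()] (tables are generated) or a list with
#'   `patients`, `visits`, `prescriptions` data frames (e.g. read from CSV).
#' @param registry a [code_registry()].
#' @param spec a [propensity_spec()].
#' @param estimand `"ATE"` (inverse-probability weights) or `"ATO"` (overlap
#'   weights).
#' @param outcomes binary outcome columns to estimate.
#' @param required_covariates complete-case requirement.
#' @return A list: `episodes` (analysis sample), `exclusion_tally`,
#'   `excluded_fraction_missing`, `n_orphan_visits`, `propensity_fit`,
#'   `weights`, `balance`, `love`, `prognostic`, `effects` (named list of
#'   [arti_ate()] objects), `diagnosis_mix`, and `ground_truth`/`true_ate`
#'   when the tables were generated.
#' @examples
#' \donttest{
#' res <- run_arti_pipeline(synth_config(n_practices = 20, seed = 7),
#'                          spec = propensity_spec(engine = "fixed"))
#' res$effects$prescribed_antibiotic
#' }
#' @export
run_arti_pipeline <- function(ehr,
                              registry = code_registry(),
                              spec = propensity_spec(),
                              estimand = c("ATE", "ATO"),
                              outcomes = c("prescribed_antibiotic",
                                           "concordant"),
                              required_covariates = c("census_division",
                                                      "race_ethnicity")) {
  estimand <- match.arg(estimand)
  gt <- NULL
  true_ate <- NULL
  if (inherits(ehr, "synth_config")) {
    ehr <- generate_ehr(ehr)
  }
  if (!is.null(ehr$ground_truth)) {
    gt <- ehr$ground_truth
    true_ate <- ehr$true_ate
  }
  cohort <- build_episodes(ehr$patients, ehr$visits, ehr$prescriptions,
                           registry)
  excl <- apply_exclusions(cohort$episodes)
  cc <- complete_case_filter(excl$episodes, required_covariates)
  ep <- attach_outcomes(cc$episodes, registry)

  fit <- fit_propensity(ep, spec)
  e <- predict(fit)
  Z <- ep$modality == "telemedicine"
  wts <- compute_weights(e, Z, if (estimand == "ATO") "ATO" else "ATE")
  bal <- balance_table(ep, spec$covariates, Z, wts$w)
  prog <- prognostic_score_balance(ep, outcomes[1], spec$covariates, Z,
                                   wts$w)
  effects <- lapply(outcomes, function(oc)
    arti_ate(ep[[oc]], Z, wts$w, ep[[spec$group]], outcome = oc,
             estimand = estimand))
  names(effects) <- outcomes

  list(episodes = ep,
       exclusion_tally = excl$tally,
       excluded_fraction_missing = cc$excluded_fraction,
       n_orphan_visits = length(cohort$orphans),
       n_unknown_codes = cohort$n_unknown_codes,
       propensity_fit = fit,
       weights = wts,
       balance = bal,
       love = love_plot_data(bal),
       prognostic = prog[c("asb_unweighted", "asb_weighted")],
       effects = effects,
       diagnosis_mix = diagnosis_mix(ep, Z, wts$w, ep[[spec$group]]),
       ground_truth = gt,
       true_ate = true_ate)
}

#' Write pipeline outputs as flat CSV files
#'
#' Writes `episodes.csv`, `weights.csv`, `balance.csv`, `love_plot.csv`,
#' `effects.csv` and `diagnosis_mix.csv` from a [run_arti_pipeline()]
#' result.
#'
#' @param res result of [run_arti_pipeline()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_csv <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                        row.names = FALSE)
  wr(res$episodes, "episodes.csv")
  wr(cbind(episode_id = res$episodes$index_visit_id,
           as.data.frame(res$weights)), "weights.csv")
  wr(as.data.frame(res$balance), "balance.csv")
  wr(res$love, "love_plot.csv")
  eff <- do.call(rbind, lapply(res$effects, function(e) data.frame(
    outcome = e$outcome, estimand = e$estimand,
    pct_inperson = e$weighted_pct[["inperson"]],
    pct_inperson_lo = e$arm_ci["inperson", 1],
    pct_inperson_hi = e$arm_ci["inperson", 2],
    pct_telemedicine = e$weighted_pct[["telemedicine"]],
    pct_telemedicine_lo = e$arm_ci["telemedicine", 1],
    pct_telemedicine_hi = e$arm_ci["telemedicine", 2],
    ate = e$ate, se_robust = e$se_robust,
    ci_lo = e$ci95[1], ci_hi = e$ci95[2],
    n_inperson = e$n_unweighted[["inperson"]],
    n_telemedicine = e$n_unweighted[["telemedicine"]],
    stringsAsFactors = FALSE)))
  wr(eff, "effects.csv")
  wr(res$diagnosis_mix, "diagnosis_mix.csv")
  invisible(dir)
}

#' Read EHR tables from a directory of CSV files
#'
#' Expects `patients.csv`, `visits.csv` and `prescriptions.csv` in the
#' package schemas (see [generate_ehr()]); `ground_truth.csv` is attached
#' when present.
#'
#' @param dir directory path.
#' @return A list usable as the `ehr` argument of [run_arti_pipeline()].
#' @export
read_ehr_csv <- function(dir) {
  rd <- function(f, ...) utils::read.csv(file.path(dir, f),
                                         stringsAsFactors = FALSE, ...)
  visits <- rd("visits.csv",
               colClasses = c(billing_modifier = "character",
                              place_of_service = "character"))
  ## empty evidence fields round-trip as NA; restore the empty string
  visits$billing_modifier[is.na(visits$billing_modifier)] <- ""
  visits$place_of_service[is.na(visits$place_of_service)] <- ""
  out <- list(patients = rd("patients.csv"), visits = visits,
              prescriptions = rd("prescriptions.csv"))
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) {
    out$ground_truth <- utils::read.csv(gt, stringsAsFactors = FALSE)
    out$true_ate <- 100 * mean(out$ground_truth$y_tele -
                                 out$ground_truth$y_inperson)
  }
  out
}
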