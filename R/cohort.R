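#' Classify visits against the code-set registry
#'
#' Splits each visit's pipe-delimited diagnosis codes and flags membership in
#' the ARTI, excluded and antibiotic-warranting code sets; flags well visits
#' by visit type. Unknown codes are ignored but counted in the returned
#' attribute `n_unknown_codes`.
#'
#' @param visits visit table with `visit_id`, `diagnosis_codes`,
#'   `visit_type`.
#' @param registry an [code_registry()] object.
#' @return `visits` with added logical columns `is_arti`, `dx_strep`,
#'   `dx_aom`, `dx_sinusitis`, `dx_viral`, `has_excluded_dx`,
#'   `has_abx_warranting_codx`, `is_well_visit`.
#' @export
classify_visits <- function(visits, registry) {
  stopifnot(inherits(registry, "arti_registry"))
  codes <- split_codes(visits$diagnosis_codes)
  member <- function(set) {
    vapply(codes, function(cc) any(cc %in% set), logical(1))
  }
  visits$dx_viral <- member(registry$arti_viral)
  visits$dx_strep <- member(registry$arti_strep)
  visits$dx_aom <- member(registry$arti_aom)
  visits$dx_sinusitis <- member(registry$arti_sinusitis)
  visits$is_arti <- visits$dx_viral | visits$dx_strep | visits$dx_aom |
    visits$dx_sinusitis
  visits$has_excluded_dx <- member(registry$excluded_dx)
  visits$has_abx_warranting_codx <- member(registry$abx_warranting_codx)
  visits$is_well_visit <- visits$visit_type %in% registry$well_visit_types
  known <- c(registry$arti_viral, registry$arti_strep, registry$arti_aom,
             registry$arti_sinusitis, registry$excluded_dx,
             registry$abx_warranting_codx)
  attr(visits, "n_unknown_codes") <-
    sum(vapply(codes, function(cc) sum(!cc %in% known), integer(1)))
  visits
}

#' Determine visit modality from billing and scheduling evidence
#'
#' A visit is telemedicine if it carries billing modifier GT or 95, a
#' telehealth place-of-service code, or video-visit metadata; otherwise it is
#' in-person (OR semantics over the three evidence channels).
#'
#' @param visits visit table with `billing_modifier`, `place_of_service`,
#'   `video_flag`.
#' @param telehealth_pos place-of-service codes indicating telehealth.
#' @return Character vector, `"telemedicine"` or `"inperson"`.
#' @export
flag_exposure <- function(visits, telehealth_pos = c("02", "10")) {
  mod <- as.character(visits$billing_modifier)
  pos <- as.character(visits$place_of_service)
  video <- as.logical(visits$video_flag) %in% TRUE
  tele <- (mod %in% c("GT", "95")) | (pos %in% telehealth_pos) | video
  ifelse(tele, "telemedicine", "inperson")
}

#' Index visits among one patient's ARTI visits
#'
#' A visit is an index visit iff the patient has no ARTI visit in the 21 days
#' before it (day offsets -21 to -1 inclusive). A same-day earlier visit makes
#' the later one a follow-up, not an index (tie-break by `(day, visit_id)`).
#'
#' @param days integer days of one patient's ARTI visits, sorted
#'   non-decreasingly (error if not).
#' @param lookback_days lookback window length, default 21.
#' @return Logical vector: is each visit an index visit.
#' @examples
#' find_index_visits(c(0, 10, 40))  # TRUE FALSE TRUE
#' @export
find_index_visits <- function(days, lookback_days = 21) {
  if (is.unsorted(days)) stop("visit days must be sorted non-decreasingly")
  n <- length(days)
  if (!n) return(logical(0))
  blocked <- vapply(seq_len(n), function(i) {
    any(days >= days[i] - lookback_days & days <= days[i] - 1)
  }, logical(1))
  ## same-day tie-break: only the first visit of a day can be the index
  !blocked & !duplicated(days)
}

#' Link follow-up ARTI visits to an index visit
#'
#' ARTI visits with day offsets 1 to `followup_days` after the index are
#' follow-ups, as are later same-day visits (tie-break by visit id).
#'
#' @param index_day day of the index visit.
#' @param days days of the same patient's ARTI visits.
#' @param visit_ids optional visit ids aligned with `days`.
#' @param index_visit_id id of the index visit (used for the same-day
#'   tie-break when `visit_ids` is given).
#' @param followup_days linkage window, default 14.
#' @return Logical selection over `days`.
#' @export
link_followups <- function(index_day, days, visit_ids = NULL,
                           index_visit_id = NULL, followup_days = 14) {
  off <- days - index_day
  sel <- off >= 0 & off <= followup_days
  if (!is.null(visit_ids) && !is.null(index_visit_id)) {
    sel <- sel & (off > 0 | visit_ids > index_visit_id)
  } else {
    sel <- sel & off > 0
  }
  sel
}

#' Link systemic antibiotic prescriptions to an index visit
#'
#' Systemic prescriptions with day offsets 0 to `abx_link_days` after the
#' index visit are linked; prescriptions before the index, after the window,
#' or that are not systemic never link.
#'
#' @param index_day day of the index visit.
#' @param rx_days prescription days for the same patient.
#' @param systemic_flag 0/1 or logical systemic indicator.
#' @param abx_link_days linkage window, default 2.
#' @return Logical selection over `rx_days`.
#' @export
link_antibiotics <- function(index_day, rx_days, systemic_flag,
                             abx_link_days = 2) {
  off <- rx_days - index_day
  off >= 0 & off <= abx_link_days & as.logical(systemic_flag)
}

## per-patient episode skeleton: index/follow-up/orphan status and anchor
## index for every ARTI visit (vectorized across the whole sorted table)
episode_status <- function(patient_id, day, lookback_days = 21,
                           followup_days = 14) {
  n <- length(day)
  if (!n)
    return(data.frame(status = character(0), anchor = integer(0)))
  new_pat <- c(TRUE, patient_id[-1] != patient_id[-n])
  prev_day <- c(NA_integer_, day[-n])
  gap <- day - prev_day
  is_index <- new_pat | (gap >= lookback_days + 1L)
  ## anchor = row of the most recent index for the same patient
  idx_row <- ifelse(is_index, seq_len(n), NA_integer_)
  anchor <- unlist(lapply(split(idx_row, cumsum(new_pat)), locf),
                   use.names = FALSE)
  offset <- day - day[anchor]
  status <- ifelse(is_index, "index",
                   ifelse(offset <= followup_days, "followup", "orphan"))
  ## a visit 15..lookback days after its anchor is an orphan: it belongs to
  ## no episode but still blocks index eligibility through the lookback rule
  anchor[status != "followup" & status != "index"] <- NA_integer_
  anchor[status == "index"] <- seq_len(n)[status == "index"]
  data.frame(status = status, anchor = anchor)
}

#' Build ARTI episodes of care from visit and prescription streams
#'
#' Classifies visits, finds index visits (no ARTI visit in the previous 21
#' days), links follow-up ARTI visits within 14 days and systemic antibiotic
#' prescriptions within 2 days of each index visit, flags exposure, and
#' attaches the covariate snapshot. Exclusion filters are applied separately
#' by [apply_exclusions()] and [complete_case_filter()].
#'
#' @param patients,visits,prescriptions tables in the package CSV schemas.
#' @param registry a [code_registry()] object.
#' @param lookback_days index-visit lookback window (default 21).
#' @param followup_days follow-up linkage window (default 14).
#' @param abx_link_days antibiotic linkage window after the index (default 2).
#' @return A list with `episodes` (one row per episode: identifiers,
#'   exposure, diagnosis flags, covariates, linked follow-up and prescription
#'   ids/offsets as pipe-joined strings), `orphans` (ARTI visits 15-21 days
#'   after their anchor, assigned to no episode) and `n_unknown_codes`.
#' @export
build_episodes <- function(patients, visits, prescriptions, registry,
                           lookback_days = 21, followup_days = 14,
                           abx_link_days = 2) {
  cl <- classify_visits(visits, registry)
  cl$modality <- flag_exposure(cl)
  arti <- cl[cl$is_arti, , drop = FALSE]
  ord <- order(arti$patient_id, arti$day, arti$visit_id)
  arti <- arti[ord, , drop = FALSE]
  st <- episode_status(arti$patient_id, arti$day, lookback_days,
                       followup_days)
  arti$status <- st$status
  arti$anchor <- st$anchor

  idx <- which(arti$status == "index")
  ep <- arti[idx, c("visit_id", "patient_id", "practice_id", "day",
                    "visit_type", "modality", "dx_strep", "dx_aom",
                    "dx_sinusitis", "dx_viral", "has_excluded_dx",
                    "has_abx_warranting_codx", "is_well_visit",
                    "clinician_specialty"), drop = FALSE]
  names(ep)[names(ep) == "visit_id"] <- "index_visit_id"
  names(ep)[names(ep) == "day"] <- "index_day"

  ## follow-up linkage: anchor row -> episode row
  fu <- arti[arti$status == "followup", c("visit_id", "day", "anchor")]
  ep_row <- match(fu$anchor, idx)
  fu_ids <- split(fu$visit_id, factor(ep_row, levels = seq_along(idx)))
  fu_off <- split(fu$day - arti$day[fu$anchor],
                  factor(ep_row, levels = seq_along(idx)))
  ep$followup_visit_ids <- join_codes(fu_ids)
  ep$followup_offsets <- join_codes(fu_off)
  ep$n_followups <- lengths(fu_ids)

  ## antibiotic linkage: systemic prescriptions 0..abx_link_days after index
  rx <- prescriptions
  rx$drug_name <- normalize_drug(rx$drug_name)
  rx <- rx[rx$systemic_flag == 1, , drop = FALSE]
  mg <- merge(ep[, c("index_visit_id", "patient_id", "index_day")], rx,
              by = "patient_id")
  mg$offset <- mg$day - mg$index_day
  lk <- mg[mg$offset >= 0 & mg$offset <= abx_link_days, , drop = FALSE]
  lk <- lk[order(lk$index_visit_id, lk$offset, lk$rx_id), , drop = FALSE]
  f <- factor(lk$index_visit_id, levels = ep$index_visit_id)
  ep$linked_rx_ids <- join_codes(split(lk$rx_id, f))
  ep$linked_rx_drugs <- join_codes(split(lk$drug_name, f))
  ep$linked_rx_offsets <- join_codes(split(lk$offset, f))
  ep$prescribed_antibiotic <- ep$linked_rx_ids != ""

  ## subsequent systemic antibiotics 3..followup_days after the index
  sub <- mg[mg$offset >= 3 & mg$offset <= followup_days, , drop = FALSE]
  fs <- factor(sub$index_visit_id, levels = ep$index_visit_id)
  ep$subsequent_rx_offsets <- join_codes(split(sub$offset, fs))

  ## covariate snapshot + derived fields
  ep <- merge(ep, patients[, setdiff(names(patients), "practice_id")],
              by = "patient_id", sort = FALSE)
  ep$age_group <- ifelse(ep$age_years < 12, "<12", ">=12")
  ep$season <- as.character(season_of_day(ep$index_day))
  ep$census_region <- division_to_region(ep$census_division)
  ep <- ep[order(ep$patient_id, ep$index_day, ep$index_visit_id), ,
           drop = FALSE]
  rownames(ep) <- NULL

  list(episodes = ep,
       orphans = arti$visit_id[arti$status == "orphan"],
       n_unknown_codes = attr(cl, "n_unknown_codes"))
}

#' Apply episode exclusion filters
#'
#' Drops episodes whose index visit carries an excluded diagnosis
#' (pneumonia, bronchiolitis, COVID-19, influenza), is coded as a well-child
#' visit, or carries a codiagnosis warranting antibiotics. Filters are
#' applied in that fixed order and each exclusion is tallied under the first
#' reason that triggered it. By default exclusion diagnoses are assessed at
#' the index visit only; episode-wide assessment would require the follow-up
#' visits' codes and is not implemented here.
#'
#' @param episodes episode table from [build_episodes()].
#' @return List with `episodes` (retained) and `tally` (named counts per
#'   exclusion reason, in order of application).
#' @export
apply_exclusions <- function(episodes) {
  reasons <- c(excluded_dx = 0L, well_visit = 0L, abx_warranting_codx = 0L)
  drop1 <- episodes$has_excluded_dx
  drop2 <- !drop1 & episodes$is_well_visit
  drop3 <- !drop1 & !drop2 & episodes$has_abx_warranting_codx
  reasons["excluded_dx"] <- sum(drop1)
  reasons["well_visit"] <- sum(drop2)
  reasons["abx_warranting_codx"] <- sum(drop3)
  list(episodes = episodes[!(drop1 | drop2 | drop3), , drop = FALSE],
       tally = reasons)
}

#' Complete-case filter on required covariates
#'
#' @param episodes episode table.
#' @param required covariates that must be non-missing.
#' @return List with `episodes` (complete cases) and `excluded_fraction`.
#' @export
complete_case_filter <- function(episodes,
                                 required = c("census_division",
                                              "race_ethnicity")) {
  absent <- setdiff(required, names(episodes))
  if (length(absent))
    stop("required covariate absent from episode table: ",
         paste(absent, collapse = ", "))
  miss <- Reduce(`|`, lapply(required, function(v) is.na(episodes[[v]])))
  list(episodes = episodes[!miss, , drop = FALSE],
       excluded_fraction = mean(miss))
}
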