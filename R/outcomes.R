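#' Primary diagnosis label for an episode
#'
#' Resolves a multi-code ARTI diagnosis set to a single label under the fixed
#' hierarchy strep > acute otitis media > sinusitis > viral: when a bacterial
#' code is present it governs the antibiotic-appropriateness judgment.
#'
#' @param strep,aom,sinusitis,viral logical vectors: which ARTI groups each
#'   episode's index diagnosis codes touch. At least one must be `TRUE` per
#'   episode (error otherwise).
#' @return Character vector of diagnosis labels (see [dx_labels()] order).
#' @examples
#' assign_primary_diagnosis(strep = TRUE, aom = FALSE,
#'                          sinusitis = FALSE, viral = TRUE)
#' @export
assign_primary_diagnosis <- function(strep, aom, sinusitis, viral) {
  if (any(!(strep | aom | sinusitis | viral)))
    stop("episode with empty ARTI diagnosis set")
  ifelse(strep, "strep_pharyngitis",
         ifelse(aom, "acute_otitis_media",
                ifelse(sinusitis, "bacterial_sinusitis", "viral_arti")))
}

#' Guideline concordance of an episode's linked antibiotics
#'
#' Diagnosis-specific first-line rules: for streptococcal pharyngitis an
#' antibiotic is required and every linked drug must be first-line
#' (amoxicillin or penicillin by default); for acute otitis media and
#' bacterial sinusitis either no systemic antibiotic or exclusively
#' first-line drugs (amoxicillin or amoxicillin-clavulanic acid) are
#' concordant; for viral ARTI only no systemic antibiotic is concordant.
#' Any non-first-line drug in the linked set renders the episode
#' non-concordant.
#'
#' @param label diagnosis label vector.
#' @param drugs list of character vectors: linked systemic drug names per
#'   episode (possibly empty). A single character vector is treated as one
#'   episode.
#' @param registry an [code_registry()] supplying the `firstline` map.
#' @return Logical vector.
#' @examples
#' reg <- code_registry()
#' score_concordance("strep_pharyngitis", list("amoxicillin"), reg)  # TRUE
#' score_concordance("viral_arti", list(character(0)), reg)          # TRUE
#' @export
score_concordance <- function(label, drugs, registry) {
  if (!is.list(drugs)) drugs <- list(drugs)
  stopifnot(length(label) == length(drugs))
  fl <- registry$firstline
  vapply(seq_along(label), function(i) {
    d <- normalize_drug(drugs[[i]])
    d <- d[nzchar(d)]
    first <- fl[[label[i]]]
    if (!length(d)) {
      ## no systemic antibiotic: concordant except for strep, whose
      ## concordant options are drugs only
      label[i] != "strep_pharyngitis"
    } else {
      length(first) > 0 && all(d %in% first)
    }
  }, logical(1))
}

#' Attach outcome records to episodes
#'
#' Computes, per episode: the primary diagnosis label and its bacterial flag,
#' antibiotic prescription and guideline concordance, follow-up visit
#' indicators in the 0-2, 3-10 and 11-14 day windows (plus their union 0-14),
#' and subsequent-antibiotic indicators in the 3-10 and 11-14 day windows
#' (plus their union 3-14). Prescriptions in days 0-2 are linked to the index
#' visit and therefore never counted as subsequent.
#'
#' @param episodes episode table from [build_episodes()].
#' @param registry an [code_registry()] object.
#' @return `episodes` with added columns `diagnosis`, `bacterial_flag`,
#'   `prescribed_antibiotic`, `concordant`, `followup_0_2`, `followup_3_10`,
#'   `followup_11_14`, `followup_0_14`, `subsequent_abx_3_10`,
#'   `subsequent_abx_11_14`, `subsequent_abx_3_14`.
#' @export
attach_outcomes <- function(episodes, registry) {
  ep <- episodes
  ep$diagnosis <- assign_primary_diagnosis(ep$dx_strep, ep$dx_aom,
                                           ep$dx_sinusitis, ep$dx_viral)
  ep$bacterial_flag <- ep$diagnosis != "viral_arti"
  drugs <- split_codes(ep$linked_rx_drugs)
  ep$prescribed_antibiotic <- lengths(drugs) > 0
  ep$concordant <- score_concordance(ep$diagnosis, drugs, registry)

  fu_off <- split_codes(ep$followup_offsets)
  in_win <- function(off_list, lo, hi) {
    vapply(off_list, function(o) {
      o <- as.numeric(o)
      any(o >= lo & o <= hi)
    }, logical(1))
  }
  ep$followup_0_2 <- in_win(fu_off, 0, 2)
  ep$followup_3_10 <- in_win(fu_off, 3, 10)
  ep$followup_11_14 <- in_win(fu_off, 11, 14)
  ep$followup_0_14 <- ep$followup_0_2 | ep$followup_3_10 | ep$followup_11_14

  rx_off <- split_codes(ep$subsequent_rx_offsets)
  ep$subsequent_abx_3_10 <- in_win(rx_off, 3, 10)
  ep$subsequent_abx_11_14 <- in_win(rx_off, 11, 14)
  ep$subsequent_abx_3_14 <- ep$subsequent_abx_3_10 | ep$subsequent_abx_11_14
  ep
}
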