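#' Diagnosis and drug code-set registry
#'
#' Classification of visits and prescriptions is driven entirely by named code
#' sets: the four ARTI diagnosis groups (viral upper respiratory infection,
#' streptococcal pharyngitis, acute otitis media, bacterial sinusitis), the
#' excluded diagnoses (pneumonia, bronchiolitis, COVID-19, influenza), the
#' antibiotic-warranting codiagnoses (e.g. urinary tract infection), the
#' well-visit type labels, the systemic antibiotic drug names, and the
#' diagnosis-specific first-line drug map used for guideline-concordance
#' scoring. Codes are symbolic strings; no ICD-10 parsing is attempted.
#'
#' @param arti_viral,arti_strep,arti_aom,arti_sinusitis character vectors of
#'   diagnosis codes for the four ARTI groups. Must be pairwise disjoint.
#' @param excluded_dx codes whose presence at the index visit excludes the
#'   episode (lower-respiratory / viral-testing presentations).
#' @param abx_warranting_codx codiagnosis codes that independently warrant
#'   antibiotics; episodes carrying one at the index visit are excluded.
#' @param well_visit_types visit-type labels marking well-child visits.
#' @param systemic_antibiotics systemic antibiotic drug names (lower case).
#' @param firstline named list mapping each diagnosis label
#'   (`strep_pharyngitis`, `acute_otitis_media`, `bacterial_sinusitis`,
#'   `viral_arti`) to its set of first-line drug names. `viral_arti` must map
#'   to an empty set: no systemic antibiotic is concordant for viral ARTI.
#' @return An object of class `arti_registry`.
#' @examples
#' reg <- code_registry()
#' reg$firstline$strep_pharyngitis
#' @export
code_registry <- function(arti_viral = c("ARTI-V1", "ARTI-V2", "ARTI-V3"),
                          arti_strep = c("ARTI-S1", "ARTI-S2"),
                          arti_aom = c("ARTI-O1", "ARTI-O2"),
                          arti_sinusitis = c("ARTI-N1", "ARTI-N2"),
                          excluded_dx = c("EXC-PNEU", "EXC-BRON",
                                          "EXC-COV", "EXC-FLU"),
                          abx_warranting_codx = c("CDX-UTI", "CDX-SSTI"),
                          well_visit_types = "well_child",
                          systemic_antibiotics = c(
                            "amoxicillin", "penicillin",
                            "amoxicillin-clavulanic acid",
                            "azithromycin", "cefdinir", "cephalexin"),
                          firstline = list(
                            strep_pharyngitis = c("amoxicillin", "penicillin"),
                            acute_otitis_media = c(
                              "amoxicillin", "amoxicillin-clavulanic acid"),
                            bacterial_sinusitis = c(
                              "amoxicillin", "amoxicillin-clavulanic acid"),
                            viral_arti = character(0))) {
  reg <- structure(list(
    arti_viral = as.character(arti_viral),
    arti_strep = as.character(arti_strep),
    arti_aom = as.character(arti_aom),
    arti_sinusitis = as.character(arti_sinusitis),
    excluded_dx = as.character(excluded_dx),
    abx_warranting_codx = as.character(abx_warranting_codx),
    well_visit_types = as.character(well_visit_types),
    systemic_antibiotics = normalize_drug(systemic_antibiotics),
    firstline = lapply(firstline, normalize_drug)
  ), class = "arti_registry")
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  arti_sets <- reg[c("arti_viral", "arti_strep", "arti_aom", "arti_sinusitis")]
  nm <- names(arti_sets)
  for (i in seq_along(arti_sets)) {
    for (j in seq_along(arti_sets)) {
      if (i < j && length(intersect(arti_sets[[i]], arti_sets[[j]])))
        stop("ARTI code sets must be pairwise disjoint: ", nm[i], " and ",
             nm[j], " overlap")
    }
  }
  if (length(intersect(reg$excluded_dx, unlist(arti_sets))))
    stop("excluded_dx must be disjoint from the ARTI code sets")
  needed <- c("strep_pharyngitis", "acute_otitis_media",
              "bacterial_sinusitis", "viral_arti")
  if (!all(needed %in% names(reg$firstline)))
    stop("firstline map must name all four diagnosis labels")
  invisible(reg)
}

#' Read a code-set registry from a YAML file
#'
#' The YAML file mirrors the arguments of [code_registry()]: one key per code
#' set, plus a `firstline` mapping of diagnosis label to drug-name list.
#'
#' @param path path to a YAML file.
#' @return An `arti_registry` object.
#' @export
read_registry_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(code_registry, y)
}

#' @export
print.arti_registry <- function(x, ...) {
  cat("ARTI code-set registry\n")
  for (nm in c("arti_viral", "arti_strep", "arti_aom", "arti_sinusitis",
               "excluded_dx", "abx_warranting_codx"))
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  cat(sprintf("  %-20s %s\n", "systemic drugs",
              paste(x$systemic_antibiotics, collapse = ", ")))
  invisible(x)
}

## canonical diagnosis labels, in concordance-hierarchy order
dx_labels <- function() {
  c("strep_pharyngitis", "acute_otitis_media",
    "bacterial_sinusitis", "viral_arti")
}
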