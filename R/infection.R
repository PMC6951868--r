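# Suspected-infection labeling (qualifying culture drawn AND qualifying IV
# anti-infective administered during the encounter) and the mortality
# outcome (in-hospital death or referral to hospice at discharge).

.QUAL_SPECIMENS <- c("blood", "body fluid", "bronchial", "catheter tip",
                     "cerebrospinal fluid", "fungal", "ova and parasites",
                     "sputum", "stool", "tissue", "urine", "wound")

.QUAL_ANTIBIOTICS <- c("ampicillin-sulbactam", "azithromycin", "cefepime",
                       "ceftriaxone", "ciprofloxacin", "clindamycin",
                       "fluconazole", "fluticasone-salmeterol",
                       "levofloxacin", "meropenem", "piperacillin-tazobactam",
                       "vancomycin")

#' Qualifying specimen and anti-infective lists
#'
#' The fixed lists that define suspected infection: a culture of one of the
#' qualifying specimen types must have been drawn AND one of the qualifying
#' anti-infectives administered intravenously during the encounter. Matching
#' is case-insensitive on the trimmed string; anything else does not qualify
#' and is logged. The list is kept exactly as defined, including
#' fluticasone-salmeterol.
#'
#' @return Character vector of qualifying specimen types / drug names.
#' @export
qualifying_specimens <- function() .QUAL_SPECIMENS

#' @rdname qualifying_specimens
#' @export
qualifying_antibiotics <- function() .QUAL_ANTIBIOTICS

.norm_str <- function(x) tolower(trimws(x))

#' Label suspected infection for every encounter
#'
#' An encounter is labeled suspected-infection positive when it has at least
#' one qualifying culture draw and at least one qualifying intravenous
#' anti-infective administration; no temporal ordering between the two is
#' required (the whole encounter is the window). Also records whether serum
#' lactate was ever measured during the encounter.
#'
#' @param cohort A `sepsis_cohort`.
#' @param quiet Suppress the message counting non-qualifying specimen/drug
#'   strings.
#' @return A `data.table`: `encounter_id`, `suspected_infection`,
#'   `first_culture_time`, `first_abx_time` (`NA` when none),
#'   `lactate_measured`.
#' @export
label_infection <- function(cohort, quiet = FALSE) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  cul <- cohort$cultures
  med <- cohort$med_admins

  cul_ok <- .norm_str(cul$specimen) %in% .QUAL_SPECIMENS
  med_ok <- .norm_str(med$drug) %in% .QUAL_ANTIBIOTICS &
    toupper(trimws(med$route)) == "IV"
  if (!quiet) {
    n_bad_spec <- sum(!.norm_str(cul$specimen) %in% .QUAL_SPECIMENS)
    n_bad_drug <- sum(!.norm_str(med$drug) %in% .QUAL_ANTIBIOTICS)
    if (n_bad_spec + n_bad_drug > 0) {
      message(sprintf(
        "infection labeling: %d non-qualifying specimen and %d non-qualifying drug rows ignored",
        n_bad_spec, n_bad_drug))
    }
  }

  encounter_id <- collect_time <- admin_time <- NULL
  first_cul <- if (any(cul_ok)) {
    cul[cul_ok, .(first_culture_time = min(collect_time)), by = encounter_id]
  } else {
    data.table::data.table(encounter_id = character(),
                           first_culture_time = parse_clinical_time(character()))
  }
  first_abx <- if (any(med_ok)) {
    med[med_ok, .(first_abx_time = min(admin_time)), by = encounter_id]
  } else {
    data.table::data.table(encounter_id = character(),
                           first_abx_time = parse_clinical_time(character()))
  }
  lact <- unique(
    cohort$observations$encounter_id[
      cohort$observations$concept == "lactate_mmol_L"])

  out <- data.table::data.table(encounter_id = cohort$encounters$encounter_id)
  out <- merge(out, first_cul, by = "encounter_id", all.x = TRUE)
  out <- merge(out, first_abx, by = "encounter_id", all.x = TRUE)
  out[, `:=`(
    suspected_infection = !is.na(first_culture_time) & !is.na(first_abx_time),
    lactate_measured = encounter_id %in% lact
  )]
  data.table::setcolorder(out, c("encounter_id", "suspected_infection",
                                 "first_culture_time", "first_abx_time",
                                 "lactate_measured"))
  out[]
}

#' Mortality outcome
#'
#' The mortality outcome is in-hospital death or referral to hospice at
#' discharge: `TRUE` when the discharge disposition is `expired` or
#' `hospice`.
#'
#' @param disposition Character vector of discharge dispositions, or a
#'   `sepsis_cohort` (in which case one value per encounter is returned).
#' @return Logical vector.
#' @export
mortality_outcome <- function(disposition) {
  if (inherits(disposition, "sepsis_cohort")) {
    disposition <- disposition$encounters$disposition
  }
  tolower(as.character(disposition)) %in% c("expired", "hospice")
}
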