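# Clinical concept registry: fixed units and physiologic plausibility bounds
# enforced at ingest. Values outside bounds are rejected, never clamped.

.CONCEPTS <- data.table::data.table(
  concept = c(
    "temperature_C", "heart_rate_bpm", "resp_rate_bpm", "wbc_per_mm3",
    "band_pct", "sbp_mmHg", "map_mmHg", "lactate_mmol_L", "bilirubin_mg_dL",
    "creatinine_mg_dL", "platelets_per_uL", "inr", "sodium_mmol_L",
    "potassium_mmol_L", "chloride_mmol_L", "spo2_pct", "loc_avpu"
  ),
  lower = c(25, 10, 0, 0, 0, 20, 10, 0, 0, 0, 0, 0.1, 80, 0.5, 50, 0, 0),
  upper = c(45, 300, 80, 5e5, 100, 350, 250, 50, 80, 40, 2e6, 20, 200, 15,
            200, 100, 3),
  is_lab = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
             TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
)

#' Clinical concept registry
#'
#' The fixed vocabulary of observation concepts the package understands, with
#' the unit each is stored in (encoded in the concept name), the physiologic
#' plausibility bounds enforced at ingest, and whether the concept is a
#' laboratory result (labs are the events eligible for corrected re-results).
#' Level of consciousness (`loc_avpu`) is stored ordinally: A = 0, V = 1,
#' P = 2, U = 3.
#'
#' @return A `data.table` with columns `concept`, `lower`, `upper`, `is_lab`.
#' @export
#' @examples
#' concept_registry()
concept_registry <- function() {
  data.table::copy(.CONCEPTS)
}

.known_concepts <- function() .CONCEPTS$concept

.lab_concepts <- function() .CONCEPTS$concept[.CONCEPTS$is_lab]

.assert_concept <- function(concept) {
  bad <- setdiff(unique(concept), .known_concepts())
  if (length(bad)) {
    stop("unknown concept(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(concept)
}
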