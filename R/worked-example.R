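# A fixed, hand-authored twelve-encounter cohort: one encounter per
# attribution class, a multiple-organ-dysfunction case, an SBP-drop-only
# case, and near-miss controls. Stable across releases; used in examples,
# the vignette and the tests.

#' Worked-example cohort
#'
#' Twelve deterministic synthetic encounters, all admitted 2016-04-01 for a
#' five-day stay, each with a normal baseline (vitals at one hour, routine
#' labs at two hours) and, where noted, a deterioration at 24 h (two SIRS
#' vitals: temperature 39.0 C, heart rate 105) with the class-defining organ
#' value at 25 h:
#'
#' * `W01` lactate 3.5 (flagged by every scenario; suspected infection:
#'   blood culture + IV vancomycin; expired)
#' * `W02` SBP-drop only: baseline SBP 150, later SBP 100 (drop 50; flagged
#'   only where the SBP-decrease parameter is enabled)
#' * `W03` MAP 60 (suspected infection: urine culture + IV ceftriaxone;
#'   hospice)
#' * `W04` bilirubin 3.0 (blood culture but only oral ciprofloxacin, so not
#'   suspected infection)
#' * `W05` bilirubin 12.0 (above the conservative cap)
#' * `W06` creatinine 1.0 rising to 2.6 (qualifies even under the
#'   conservative delta rule)
#' * `W07` platelets 80 000 (IV meropenem but no culture)
#' * `W08` INR 2.0
#' * `W09` lactate 3.0 + creatinine 2.8 together (multiple organ dysfunction)
#' * `W10` control, fully normal
#' * `W11` control, SIRS alone (no organ criterion, never flagged)
#' * `W12` control, lactate 2.5 alone (no SIRS; blood culture + IV meropenem,
#'   suspected infection without a flag)
#'
#' @return A list with `cohort` (a `sepsis_cohort`) and `ground_truth`
#'   (expected flag/attribution per scenario preset plus infection and
#'   mortality labels).
#' @export
#' @examples
#' we <- worked_example_cohort()
#' screen_cohort(we$cohort, scenario_preset("sep2_based"))
worked_example_cohort <- function() {
  t0 <- "2016-04-01 00:00"
  hh <- function(h) format_clinical_time(parse_clinical_time(t0) + in_hours(h))
  ids <- sprintf("W%02d", 1:12)

  encounters <- data.table::data.table(
    encounter_id = ids,
    age_years = c(71, 58, 80, 66, 54, 62, 45, 69, 77, 50, 61, 73),
    sex = rep(c("female", "male"), 6),
    admit_time = t0,
    discharge_time = hh(120),
    disposition = c("expired", rep("home_or_other", 1), "hospice",
                    rep("home_or_other", 9)),
    icu_within_48h = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                       TRUE, FALSE, FALSE, FALSE)
  )

  base_rows <- function(id, sbp1 = 120) {
    data.table::data.table(
      encounter_id = id,
      concept = c("temperature_C", "heart_rate_bpm", "resp_rate_bpm",
                  "spo2_pct", "sbp_mmHg", "map_mmHg", "loc_avpu",
                  "sodium_mmol_L", "potassium_mmol_L", "chloride_mmol_L",
                  "wbc_per_mm3", "creatinine_mg_dL", "platelets_per_uL",
                  "bilirubin_mg_dL", "inr"),
      value = c(37.0, 72, 15, 98, sbp1, 85, 0, 140, 4.0, 104,
                8000, 1.0, 250e3, 0.8, 1.1),
      event_time = c(rep(hh(1), 10), rep(hh(2), 5))
    )
  }
  sirs_rows <- function(id) {
    data.table::data.table(
      encounter_id = id,
      concept = c("temperature_C", "heart_rate_bpm"),
      value = c(39.0, 105),
      event_time = hh(24)
    )
  }
  organ_row <- function(id, concept, value, at = 25) {
    data.table::data.table(encounter_id = id, concept = concept,
                           value = value, event_time = hh(at))
  }

  obs <- data.table::rbindlist(c(
    lapply(ids[-2], base_rows),
    list(base_rows("W02", sbp1 = 150)),
    lapply(c(ids[1:9], "W11"), sirs_rows),
    list(
      organ_row("W01", "lactate_mmol_L", 3.5),
      organ_row("W02", "sbp_mmHg", 100),
      organ_row("W03", "map_mmHg", 60),
      organ_row("W04", "bilirubin_mg_dL", 3.0),
      organ_row("W05", "bilirubin_mg_dL", 12.0),
      organ_row("W06", "creatinine_mg_dL", 2.6),
      organ_row("W07", "platelets_per_uL", 80e3),
      organ_row("W08", "inr", 2.0),
      organ_row("W09", "lactate_mmol_L", 3.0),
      organ_row("W09", "creatinine_mg_dL", 2.8),
      organ_row("W12", "lactate_mmol_L", 2.5)
    )
  ), use.names = TRUE)
  obs[, update_seq := 0L]

  cultures <- data.table::data.table(
    encounter_id = c("W01", "W03", "W04", "W12"),
    specimen = c("blood", "urine", "blood", "blood"),
    collect_time = hh(c(24, 26, 24, 10))
  )
  med_admins <- data.table::data.table(
    encounter_id = c("W01", "W03", "W04", "W07", "W12"),
    drug = c("vancomycin", "ceftriaxone", "ciprofloxacin", "meropenem",
             "meropenem"),
    route = c("IV", "IV", "PO", "IV", "IV"),
    admin_time = hh(c(26, 28, 26, 26, 12))
  )

  ground_truth <- data.table::data.table(
    encounter_id = ids,
    septic_profile = c(rep(TRUE, 9), rep(FALSE, 3)),
    planted_parameters = c("lactate", "sbp_drop", "sbp_or_map", "bilirubin",
                           "bilirubin", "creatinine", "platelets", "inr",
                           "lactate,creatinine", "", "", ""),
    class_sep2_based = c("lactate", "sbp_drop", "sbp_or_map", "bilirubin",
                         "bilirubin", "creatinine", "platelets", "inr",
                         "mods", NA, NA, NA),
    class_near_sep2 = c("lactate", NA, "sbp_or_map", "bilirubin", "bilirubin",
                        "creatinine", "platelets", "inr", "mods", NA, NA, NA),
    class_conservative = c("lactate", NA, "sbp_or_map", "bilirubin", NA,
                           "creatinine", NA, NA, "mods", NA, NA, NA),
    infected = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, TRUE),
    died_or_hospice = c(TRUE, FALSE, TRUE, rep(FALSE, 9))
  )

  list(cohort = as_cohort(encounters, obs, cultures, med_admins,
                          quiet = TRUE),
       ground_truth = ground_truth)
}
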