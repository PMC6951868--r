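# Shared builders for tiny in-code fixtures.

t_at <- function(h) parse_clinical_time("2016-05-01 00:00") + in_hours(h)

# single-encounter event table from (concept, hour, value[, seq]) triples
ev_at <- function(concept, hours, values, seq = 0L, id = "E1") {
  observation_events(id, concept, values, t_at(hours), update_seq = seq)
}

one_encounter <- function(id = "E1", los_h = 120, age = 60, sex = "male",
                          disposition = "home_or_other") {
  data.table::data.table(
    encounter_id = id, age_years = age, sex = sex,
    admit_time = t_at(0), discharge_time = t_at(los_h),
    disposition = disposition, icu_within_48h = FALSE
  )
}

empty_cultures <- function() {
  data.table::data.table(encounter_id = character(), specimen = character(),
                         collect_time = parse_clinical_time(character()))
}

empty_meds <- function() {
  data.table::data.table(encounter_id = character(), drug = character(),
                         route = character(),
                         admin_time = parse_clinical_time(character()))
}

# small cached synthetic cohort reused across test files
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(n_encounters = 250, seed = 11))
    }
    cache
  }
})
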