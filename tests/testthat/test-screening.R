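# Rules engine: SIRS, organ dysfunction, baseline SBP, attribution,
# scenario presets and the screen conjunction.

cfg <- scenario_preset("sep2_based")

test_that("SIRS criteria respect thresholds, lookbacks and absence", {
  tl <- resolve_timeline(rbind(
    ev_at("temperature_C", 10, 39.0),
    ev_at("heart_rate_bpm", 12, 95),
    ev_at("resp_rate_bpm", 12, 16),
    ev_at("wbc_per_mm3", 11, 9000)
  ))
  expect_setequal(eval_sirs(tl, t_at(14), cfg), c("temperature", "heart_rate"))

  # absent data: nothing met
  expect_length(eval_sirs(resolve_timeline(ev_at("inr", 1, 1.0)),
                          t_at(2), cfg), 0)

  # values exactly at the strict thresholds never trigger
  boundary <- resolve_timeline(rbind(
    ev_at("temperature_C", 10, 38.3),
    ev_at("heart_rate_bpm", 10, 90),
    ev_at("resp_rate_bpm", 10, 20),
    ev_at("wbc_per_mm3", 10, 12000),
    ev_at("band_pct", 10, 10)
  ))
  expect_length(eval_sirs(boundary, t_at(11), cfg), 0)

  # band forms above 10% satisfy the WBC criterion on their own
  bands <- resolve_timeline(ev_at("band_pct", 10, 11))
  expect_equal(eval_sirs(bands, t_at(11), cfg), "wbc")

  # a 30-h-old reading is outside the lookback
  old <- resolve_timeline(ev_at("temperature_C", 0, 39.5))
  expect_length(eval_sirs(old, t_at(30), cfg), 0)
  expect_equal(eval_sirs(old, t_at(29.9), cfg), "temperature")
})

test_that("baseline SBP is the earliest reading in the 30-h window", {
  tl <- resolve_timeline(ev_at("sbp_mmHg", c(10, 29), c(150, 100)))
  expect_equal(baseline_sbp(tl, t_at(30)), 150)
  expect_equal(baseline_sbp(resolve_timeline(ev_at("sbp_mmHg", 5, 132)),
                            t_at(10)), 132)
  # only reading is 31 h old -> no baseline
  expect_true(is.na(baseline_sbp(resolve_timeline(ev_at("sbp_mmHg", 0, 120)),
                                 t_at(31))))
})

test_that("SBP-drop fires only where enabled and only on a real drop", {
  tl <- resolve_timeline(ev_at("sbp_mmHg", c(5, 20), c(150, 105)))
  expect_equal(eval_organ_dysfunction(tl, t_at(21), cfg), "sbp_drop")
  expect_length(
    eval_organ_dysfunction(tl, t_at(21), scenario_preset("near_sep2")), 0)
  # a drop of exactly the threshold does not qualify (strict >40)
  tl40 <- resolve_timeline(ev_at("sbp_mmHg", c(5, 20), c(150, 110)))
  expect_length(eval_organ_dysfunction(tl40, t_at(21), cfg), 0)
})

test_that("lactate honours its 12-h lookback; inclusive lab thresholds hold", {
  lac <- resolve_timeline(ev_at("lactate_mmol_L", 10, 2.5))
  expect_equal(eval_organ_dysfunction(lac, t_at(20), cfg), "lactate")
  expect_length(eval_organ_dysfunction(lac, t_at(23), cfg), 0)  # 13 h old
  # lactate exactly 2.0 is strict and does not trigger
  expect_length(eval_organ_dysfunction(
    resolve_timeline(ev_at("lactate_mmol_L", 10, 2.0)), t_at(11), cfg), 0)
  # bilirubin and creatinine thresholds are inclusive (>= 2.0)
  expect_equal(eval_organ_dysfunction(
    resolve_timeline(ev_at("bilirubin_mg_dL", 10, 2.0)), t_at(11), cfg),
    "bilirubin")
  expect_equal(eval_organ_dysfunction(
    resolve_timeline(ev_at("creatinine_mg_dL", 10, 2.0)), t_at(11), cfg),
    "creatinine")
})

test_that("the conservative preset caps bilirubin and requires a rise in creatinine", {
  cons <- scenario_preset("conservative")
  bili12 <- resolve_timeline(ev_at("bilirubin_mg_dL", 10, 12.0))
  expect_equal(eval_organ_dysfunction(bili12, t_at(11), cfg), "bilirubin")
  expect_length(eval_organ_dysfunction(bili12, t_at(11), cons), 0)

  # flat high creatinine meets the plain rule but not the delta rule
  flat <- resolve_timeline(ev_at("creatinine_mg_dL", c(5, 30), c(2.2, 2.3)))
  expect_equal(eval_organ_dysfunction(flat, t_at(31), cfg), "creatinine")
  expect_length(eval_organ_dysfunction(flat, t_at(31), cons), 0)
  rising <- resolve_timeline(
    ev_at("creatinine_mg_dL", c(5, 30), c(1.2, 2.4)))
  expect_equal(eval_organ_dysfunction(rising, t_at(31), cons), "creatinine")
  # the rise must END at the qualifying high value, not merely span it
  falling <- resolve_timeline(
    ev_at("creatinine_mg_dL", c(5, 30), c(2.8, 1.1)))
  expect_length(eval_organ_dysfunction(falling, t_at(31), cons), 0)

  # platelets / INR are eliminated entirely
  hema <- resolve_timeline(rbind(ev_at("platelets_per_uL", 10, 8e4),
                                 ev_at("inr", 10, 2.0)))
  expect_setequal(eval_organ_dysfunction(hema, t_at(11), cfg),
                  c("platelets", "inr"))
  expect_length(eval_organ_dysfunction(hema, t_at(11), cons), 0)
})

test_that("attribution is mods across systems, precedence within a system", {
  expect_equal(attribute_class(c("lactate", "creatinine")), "mods")
  expect_equal(attribute_class(c("sbp_drop", "lactate")), "sbp_drop")
  expect_equal(attribute_class(c("sbp_or_map", "lactate")), "sbp_or_map")
  expect_equal(attribute_class(c("platelets", "inr")), "platelets")
  expect_equal(attribute_class("bilirubin"), "bilirubin")
  expect_equal(attribute_class(c("sbp_drop", "sbp_or_map", "lactate",
                                 "bilirubin")), "mods")
  expect_error(attribute_class(character()), "empty")
  expect_error(attribute_class("nonsense"), "unknown organ parameter")
})

test_that("the screen requires SIRS and organ dysfunction in conjunction", {
  enc <- one_encounter()
  # two SIRS criteria but never an organ criterion: silent
  sirs_only <- resolve_timeline(rbind(
    ev_at("temperature_C", 10, 39.5),
    ev_at("heart_rate_bpm", 10, 110),
    ev_at("lactate_mmol_L", 11, 1.2)
  ))
  r <- screen_encounter(enc, sirs_only, cfg)
  expect_false(r$flagged)
  expect_true(is.na(r$attributed_class))

  # organ value arriving one hour after the SIRS pair: alert at that instant
  full <- resolve_timeline(rbind(
    ev_at("temperature_C", 10, 39.5),
    ev_at("heart_rate_bpm", 10, 110),
    ev_at("lactate_mmol_L", 11, 3.0)
  ))
  r2 <- screen_encounter(enc, full, cfg)
  expect_true(r2$flagged)
  expect_equal(r2$first_alert_time, t_at(11))
  expect_equal(r2$attributed_class, "lactate")
  expect_setequal(r2$sirs_criteria_met, c("temperature", "heart_rate"))

  bad <- one_encounter()
  bad$discharge_time <- bad$admit_time - 10
  expect_error(screen_encounter(bad, full, cfg), "after admit_time")
})

test_that("scenario flags nest as presets grow more constrained", {
  g <- small_synth()
  a_sep2 <- screen_cohort(g$cohort, scenario_preset("sep2_based"))
  a_near <- screen_cohort(g$cohort, scenario_preset("near_sep2"))
  a_cons <- screen_cohort(g$cohort, scenario_preset("conservative"))
  f <- function(a) a$encounter_id[a$flagged]
  expect_true(all(f(a_cons) %in% f(a_near)))
  expect_true(all(f(a_near) %in% f(a_sep2)))
  # attribution partition: class counts sum to the flagged count
  for (a in list(a_sep2, a_near, a_cons)) {
    expect_equal(sum(table(a$attributed_class[a$flagged])), sum(a$flagged))
    expect_false(any(is.na(a$attributed_class[a$flagged])))
  }
  # an encounter that never depended on the SBP-drop parameter is unmoved
  unaffected <- a_sep2$encounter_id[a_sep2$flagged &
                                      a_sep2$attributed_class != "sbp_drop"]
  near_flagged <- f(a_near)
  expect_true(all(unaffected %in% near_flagged))
})
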