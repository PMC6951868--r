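# Evaluation layer: confusion-matrix metrics, Woolf odds ratios, logistic
# mortality models and the report bundle.

# Construct alert/infection label tables with prescribed counts. Encounters
# 1..n_ref_flagged are flagged by the reference; the first n_infected of
# them are the suspected-infection patients.
label_fixture <- function(n_total, flagged_ids, infected_ids,
                          classes = NULL, scenario = "x") {
  ids <- sprintf("P%05d", seq_len(n_total))
  alerts <- data.table::data.table(
    encounter_id = ids,
    flagged = seq_len(n_total) %in% flagged_ids,
    attributed_class = NA_character_)
  if (!is.null(classes)) {
    alerts$attributed_class[match(names(classes), ids)] <- unname(classes)
  } else {
    alerts$attributed_class[alerts$flagged] <- "lactate"
  }
  data.table::setattr(alerts, "scenario", scenario)
  alerts
}

test_that("scenario metrics reproduce the reference worked example", {
  n <- 15000
  ids <- sprintf("P%05d", seq_len(n))
  infected_ids <- 1:2472
  inf <- data.table::data.table(
    encounter_id = ids,
    suspected_infection = seq_len(n) %in% infected_ids,
    lactate_measured = seq_len(n) %in% 1:1999)

  ref <- label_fixture(n, 1:3862, infected_ids, scenario = "sep2_based")
  near <- label_fixture(n, c(1:2147, 2473:3467), infected_ids,
                        scenario = "near_sep2")
  cons <- label_fixture(n, c(1:1843, 2473:3227), infected_ids,
                        scenario = "conservative")

  e_ref <- evaluate_scenario(ref, inf)
  e_near <- evaluate_scenario(near, inf, ref)
  e_cons <- evaluate_scenario(cons, inf, ref)

  expect_equal(e_ref$n_flagged, 3862)
  expect_equal(e_ref$n_flagged_infected, 2472)
  expect_equal(round(100 * e_ref$ppv), 64)
  expect_equal(e_ref$sensitivity, 1)
  expect_equal(e_ref$relative_change_vs_reference, 0)
  expect_equal(round(100 * e_ref$lactate_measured_prop), 81)

  expect_equal(e_near$n_flagged, 3142)
  expect_equal(round(100 * e_near$ppv), 68)
  expect_equal(round(100 * e_near$sensitivity), 87)
  expect_equal(round(100 * e_near$relative_change_vs_reference), -19)

  expect_equal(e_cons$n_flagged, 2598)
  expect_equal(round(100 * e_cons$ppv), 71)
  expect_equal(round(100 * e_cons$sensitivity), 75)
  expect_equal(round(100 * e_cons$relative_change_vs_reference), -33)
})

test_that("identical alerts give sensitivity 1 and zero relative change", {
  a <- label_fixture(100, 1:40, 1:30)
  inf <- data.table::data.table(encounter_id = sprintf("P%05d", 1:100),
                                suspected_infection = 1:100 %in% 1:30)
  e <- evaluate_scenario(a, inf, a)
  expect_equal(e$sensitivity, 1)
  expect_equal(e$relative_change_vs_reference, 0)
})

test_that("zero flagged encounters give an NA PPV with a warning", {
  a <- label_fixture(50, integer(), 1:10)
  inf <- data.table::data.table(encounter_id = sprintf("P%05d", 1:50),
                                suspected_infection = 1:50 %in% 1:10)
  expect_warning(e <- evaluate_scenario(a, inf), "PPV undefined")
  expect_true(is.na(e$ppv))
})

test_that("Woolf crude odds ratios match the hand-computed intervals", {
  o1 <- or_2x2(118, 540 - 118, 286, 1607 - 286)
  expect_equal(round(o1$or, 2), 1.29)
  expect_equal(round(o1$ci_lower, 2), 1.02)
  expect_equal(round(o1$ci_upper, 2), 1.64)

  o2 <- or_2x2(165, 646 - 165, 215, 1197 - 215)
  expect_equal(round(o2$or, 2), 1.57)
  expect_equal(round(o2$ci_lower, 2), 1.24)
  expect_equal(round(o2$ci_upper, 2), 1.97)

  expect_warning(oz <- or_2x2(0, 10, 5, 5), "continuity")
  expect_true(is.finite(oz$or))
  expect_error(or_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("substitution analysis restricts to dual members and builds the 2x2", {
  n <- 3000
  ids <- sprintf("P%05d", seq_len(n))
  # 2147 dual-membership infected patients: 540 reclassified (118 deaths),
  # 1607 same-class (286 deaths)
  reclassified <- 1:540
  same <- 541:2147
  ref_classes <- stats::setNames(rep("lactate", 2147), ids[1:2147])
  cmp_classes <- stats::setNames(
    c(rep("creatinine", 540), rep("lactate", 1607)), ids[1:2147])
  a_ref <- label_fixture(n, 1:2500, 1:2147, classes = ref_classes,
                         scenario = "sep2_based")
  a_cmp <- label_fixture(n, 1:2147, 1:2147, classes = cmp_classes,
                         scenario = "near_sep2")
  inf <- data.table::data.table(encounter_id = ids,
                                suspected_infection = seq_len(n) %in% 1:2147)
  mort <- data.table::data.table(
    encounter_id = ids,
    died = seq_len(n) %in% c(reclassified[1:118], same[1:286]))

  s <- substitution_analysis(a_ref, a_cmp, inf, mort)
  expect_equal(s$n_dual_membership, 2147)
  expect_equal(s$n_reclassified, 540)
  expect_equal(round(100 * s$mortality_rate_reclassified), 22)
  expect_equal(round(100 * s$mortality_rate_same), 18)
  expect_equal(round(s$crude_or, 2), 1.29)
  expect_equal(round(s$ci_lower, 2), 1.02)
  expect_equal(round(s$ci_upper, 2), 1.64)
  expect_equal(s$reclass_distribution$new_class, "creatinine")
  expect_equal(s$reclass_distribution$system, "renal")
  expect_equal(s$reclass_distribution$proportion, 1)

  # identical death proportions on both sides: OR exactly 1
  expect_equal(or_2x2(20, 80, 10, 40)$or, 1, tolerance = 1e-12)
})

test_that("a covariate-free logistic fit equals the closed-form crude OR", {
  set.seed(501)
  for (i in 1:8) {
    cells <- sample(5:60, 4)  # a, b (exposed), c, d (reference)
    d <- data.table::data.table(
      died = rep(c(TRUE, FALSE, TRUE, FALSE), cells),
      attributed_class = rep(c("lactate", "lactate", "inr", "inr"), cells))
    fit <- fit_mortality_model(d, "lactate", covariates = character())
    closed <- or_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(fit$odds_ratio - closed$or), 1e-6)
  }
})

test_that("Wald intervals cover a null odds ratio at close to nominal rate", {
  set.seed(502)
  covered <- 0L
  for (i in 1:100) {
    d <- data.table::data.table(
      died = runif(400) < 0.15,
      attributed_class = ifelse(runif(400) < 0.4, "lactate", "inr"))
    fit <- fit_mortality_model(d, "lactate", covariates = character())
    if (fit$ci_lower <= 1 && 1 <= fit$ci_upper) covered <- covered + 1L
  }
  expect_gte(covered, 93L)
})

test_that("separation and missing columns are reported, never silent", {
  d <- data.table::data.table(
    died = rep(c(TRUE, FALSE), c(20, 20)),
    attributed_class = rep(c("lactate", "inr"), c(20, 20)))
  expect_warning(fit <- fit_mortality_model(d, "lactate",
                                            covariates = character()),
                 "separation|failed")
  expect_false(fit$converged)
  expect_match(fit$status, "separation")

  expect_error(fit_mortality_model(d[, .(died)], "lactate"), "lacks column")
  expect_error(fit_mortality_model(d, "not_a_class"))
})

test_that("the report bundle is deterministic and partition-consistent", {
  we <- worked_example_cohort()
  ref <- screen_cohort(we$cohort, scenario_preset("sep2_based"))
  near <- screen_cohort(we$cohort, scenario_preset("near_sep2"))
  inf <- label_infection(we$cohort, quiet = TRUE)
  evs <- list(evaluate_scenario(ref, inf),
              evaluate_scenario(near, inf, ref))
  rep1 <- build_report(evs)
  rep2 <- build_report(evs)
  expect_identical(rep1, rep2)
  att <- rep1$attribution_table
  for (sc in unique(att$scenario)) {
    expect_equal(sum(att$n_flagged[att$scenario == sc]),
                 rep1$scenario_metrics$n_flagged[
                   rep1$scenario_metrics$scenario == sc])
  }

  dir <- withr::local_tempdir()
  build_report(evs, out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("scenario_metrics.csv", "attribution_table.csv",
           "substitution.csv", "mortality_models.csv")))))

  # empty flagged set: explicit no-alerts marker, not a silent gap
  none <- data.table::data.table(encounter_id = we$ground_truth$encounter_id,
                                 flagged = FALSE,
                                 attributed_class = NA_character_)
  data.table::setattr(none, "scenario", "empty")
  suppressWarnings(e0 <- evaluate_scenario(none, inf))
  r0 <- build_report(list(e0))
  expect_true(r0$scenario_metrics$no_alerts)
  expect_equal(r0$attribution_table$attributed_class, "no_alerts")
})
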