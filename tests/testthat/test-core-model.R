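# Event store: update resolution, window queries, cohort IO.

test_that("update resolution keeps only the highest correction per event", {
  ev <- ev_at("lactate_mmol_L", c(10, 10), c(3.1, 2.0), seq = c(0L, 1L))
  tl <- resolve_timeline(ev)
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$value, 2.0)

  single <- ev_at("lactate_mmol_L", 5, 1.4)
  tl1 <- resolve_timeline(single)
  expect_equal(nrow(tl1), 1L)
  expect_equal(tl1$value, 1.4)
  expect_equal(attr(tl1, "encounter_id"), "E1")
})

test_that("resolution is permutation-invariant and idempotent", {
  set.seed(401)
  ev <- ev_at(rep(c("lactate_mmol_L", "sbp_mmHg"), c(3, 2)),
              c(1, 4, 9, 2, 7), c(1.1, 2.2, 3.3, 120, 100))
  ref <- resolve_timeline(ev)
  for (i in 1:20) {
    shuffled <- ev[sample(nrow(ev)), ]
    expect_equal(resolve_timeline(shuffled), ref, ignore_attr = TRUE)
  }
  # re-wrap the resolved timeline as events and resolve again
  rewrapped <- observation_events("E1", ref$concept, ref$value,
                                  ref$event_time)
  expect_equal(resolve_timeline(rewrapped), ref, ignore_attr = TRUE)
})

test_that("resolution rejects mixed encounters and tied counters", {
  ev <- rbind(ev_at("inr", 1, 1.2), ev_at("inr", 2, 1.3, id = "E2"))
  expect_error(resolve_timeline(ev), "multiple encounters")
  tie <- ev_at("inr", c(1, 1), c(1.2, 1.4), seq = c(0L, 0L))
  expect_error(resolve_timeline(tie), "tied update_seq")
  empty <- resolve_timeline(ev_at("inr", numeric(), numeric()))
  expect_equal(nrow(empty), 0L)
})

test_that("window query uses the half-open (at - lookback, at] interval", {
  tl <- resolve_timeline(
    ev_at("lactate_mmol_L", c(-13, -2) + 24, c(2.5, 2.8)))
  w <- window_values(tl, "lactate_mmol_L", t_at(24), lookback_h = 12)
  expect_equal(w$value, 2.8)

  # a reading exactly lookback hours old is excluded; one at `at` included
  tl2 <- resolve_timeline(ev_at("lactate_mmol_L", c(12, 24), c(1.0, 2.0)))
  w2 <- window_values(tl2, "lactate_mmol_L", t_at(24), lookback_h = 12)
  expect_equal(w2$value, 2.0)

  expect_error(window_values(tl, "unknown_thing", t_at(24), 12),
               "unknown concept")
})

test_that("window query agrees with a brute-force scan on random instants", {
  set.seed(402)
  hours <- sort(sample(seq(0, 200, by = 0.25), 100))
  vals <- round(runif(100, 0.5, 4), 2)
  tl <- resolve_timeline(ev_at("lactate_mmol_L", hours, vals))
  for (at_h in c(24, 60.25, 113, 199.5)) {
    for (lb in c(12, 30, 72)) {
      got <- window_values(tl, "lactate_mmol_L", t_at(at_h), lb)
      keep <- hours > at_h - lb & hours <= at_h
      expect_equal(got$value, vals[keep])
      expect_equal(as.numeric(got$event_time), as.numeric(t_at(hours[keep])))
    }
  }
})

test_that("cohort round-trips through CSV identically", {
  g <- small_synth()
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, dir)
  back <- read_cohort(dir, quiet = TRUE)
  for (tb in names(g$cohort)) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(g$cohort[[tb]]),
                 ignore_attr = TRUE)
  }
})

test_that("the columnar-binary dialect mirrors the CSV schema", {
  g <- small_synth()
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, dir, dialect = "parquet")
  back <- read_cohort(dir, dialect = "parquet", quiet = TRUE)
  expect_equal(as.data.frame(back$observations),
               as.data.frame(g$cohort$observations), ignore_attr = TRUE)
  expect_equal(as.data.frame(back$encounters),
               as.data.frame(g$cohort$encounters), ignore_attr = TRUE)
})

test_that("ingest rejects malformed rows and counts them, never clamps", {
  enc <- one_encounter()
  obs <- rbind(
    data.table::data.table(encounter_id = "E1", concept = "temperature_C",
                           value = 37, event_time = "2016-05-01 01:00",
                           update_seq = 0L),
    data.table::data.table(encounter_id = "E1", concept = "temperature_C",
                           value = 38, event_time = "not-a-time",
                           update_seq = 0L),
    data.table::data.table(encounter_id = "E1", concept = "temperature_C",
                           value = 90, event_time = "2016-05-01 03:00",
                           update_seq = 0L),  # implausible, must be rejected
    data.table::data.table(encounter_id = "E1", concept = "made_up",
                           value = 1, event_time = "2016-05-01 04:00",
                           update_seq = 0L)
  )
  co <- as_cohort(enc, obs, empty_cultures(), empty_meds(), quiet = TRUE)
  expect_equal(nrow(co$observations), 1L)
  expect_equal(co$observations$value, 37)
  rep <- attr(co, "ingest_report")$observations
  expect_equal(rep$rows_rejected, 3)
  expect_equal(rep$reasons$unparseable_timestamp, 1)
  expect_equal(rep$reasons$value_outside_bounds, 1)
  expect_equal(rep$reasons$unknown_concept, 1)
})

test_that("ingest enforces encounter invariants and required columns", {
  enc <- rbind(one_encounter("A"), one_encounter("B", age = 15),
               one_encounter("C"))
  enc$discharge_time[3] <- enc$admit_time[3]  # not after admit
  co <- as_cohort(enc, data.table::data.table(
    encounter_id = "A", concept = "inr", value = 1.1,
    event_time = "2016-05-01 01:00", update_seq = 0L),
    empty_cultures(), empty_meds(), quiet = TRUE)
  expect_equal(co$encounters$encounter_id, "A")
  expect_equal(attr(co, "ingest_report")$encounters$rows_rejected, 2)

  expect_error(
    as_cohort(one_encounter()[, -"sex"], co$observations,
              empty_cultures(), empty_meds(), quiet = TRUE),
    "missing required column.*sex")
})

test_that("tied update counters are rejected at ingest", {
  obs <- data.table::data.table(
    encounter_id = "E1", concept = "inr", value = c(1.1, 1.3),
    event_time = "2016-05-01 01:00", update_seq = 0L)
  co <- as_cohort(one_encounter(), obs, empty_cultures(), empty_meds(),
                  quiet = TRUE)
  expect_equal(nrow(co$observations), 0L)
  expect_equal(attr(co, "ingest_report")$observations$reasons$update_seq_tie,
               2)
})
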