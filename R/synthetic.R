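# Synthetic EHR cohort generator. Encounters carry per-encounter ground
# truth; septic-profile encounters are built so that the full SEP-2-based
# screen recovers them exactly (two SIRS-satisfying observations plus the
# planted organ-dysfunction values inside their lookbacks), while control
# encounters may satisfy SIRS alone or one organ criterion alone but never
# both in temporal conjunction.

.DEFAULT_CLASS_WEIGHTS <- c(sbp_drop = 0.280, sbp_or_map = 0.186,
                            lactate = 0.197, bilirubin = 0.031,
                            creatinine = 0.023, mods = 0.102,
                            platelets = 0.072, inr = 0.109)

# Relative suspected-infection propensity by planted class, mirroring the
# pattern that the SBP-decrease parameter is the least reliable and lactate
# the most; rescaled at generation time so the class-weighted mean equals
# frac_infected_given_flagged.
.CLASS_INFECTION_REL <- c(sbp_drop = 0.53, sbp_or_map = 0.61, lactate = 0.85,
                          bilirubin = 0.57, creatinine = 0.50, mods = 0.72,
                          platelets = 0.67, inr = 0.56)

.DEFAULT_MORTALITY_OR <- c(sbp_drop = 1.2, sbp_or_map = 1.6, lactate = 1.5,
                           bilirubin = 1.4, creatinine = 1.7,
                           platelets = 1.3, inr = 1.3)

#' Specify a synthetic cohort
#'
#' Parameters of the synthetic-EHR generator. Defaults describe the cohort
#' the package's analyses assume: about a quarter of encounters carry septic
#' physiology, planted parameter classes follow the mix observed in severe
#' sepsis surveillance (the SBP-decrease parameter the most frequent single
#' class), suspected infection among flagged encounters averages 64%, and
#' mortality follows a logistic model over the planted parameter classes.
#'
#' @param n_encounters Number of encounters (>= 1).
#' @param seed Integer seed; the full generation is deterministic given it.
#' @param frac_septic_physiology Proportion of encounters with a planted
#'   septic profile (these, and only these, are flagged by the SEP-2-based
#'   screen).
#' @param frac_infected_given_flagged Mean suspected-infection proportion
#'   among septic-profile encounters; realized per planted class with the
#'   relative reliability pattern described above.
#' @param frac_infected_background Suspected-infection proportion among
#'   control encounters.
#' @param frac_secondary_param Probability that a septic encounter whose
#'   primary planted parameter is invisible to a stricter scenario (SBP
#'   decrease, platelets, INR, or bilirubin above the conservative cap)
#'   receives a second, later planted parameter. This is what produces
#'   scenario substitution effects in synthetic cohorts.
#' @param class_weights Named sampling weights over
#'   `c(alert_classes())` for the primary planted class.
#' @param mortality_base_rate Mortality probability with no planted
#'   parameters.
#' @param mortality_or_per_parameter Named odds multipliers per planted
#'   parameter class (a `mods` plant contributes its two component
#'   parameters).
#' @param obs_interval_h Mean hours between routine vital-sign observations.
#' @param update_rate Proportion of laboratory events that receive a
#'   corrected re-result (see [plant_update_noise()]).
#' @param los_days_median Median length of stay in days (log-normal;
#'   truncated to 0.5--30 days).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_encounters = 1000,
                        seed = 1L,
                        frac_septic_physiology = 0.26,
                        frac_infected_given_flagged = 0.64,
                        frac_infected_background = 0.15,
                        frac_secondary_param = 0.35,
                        class_weights = .DEFAULT_CLASS_WEIGHTS,
                        mortality_base_rate = 0.12,
                        mortality_or_per_parameter = .DEFAULT_MORTALITY_OR,
                        obs_interval_h = 4,
                        update_rate = 0.10,
                        los_days_median = 4) {
  if (n_encounters < 1) stop("n_encounters must be >= 1", call. = FALSE)
  props <- c(frac_septic_physiology, frac_infected_given_flagged,
             frac_infected_background, frac_secondary_param,
             mortality_base_rate, update_rate)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(mortality_or_per_parameter <= 0)) {
    stop("odds multipliers must be > 0", call. = FALSE)
  }
  stopifnot(all(names(class_weights) %in% alert_classes()),
            sum(class_weights) > 0, los_days_median > 0, obs_interval_h > 0)
  structure(list(
    n_encounters = as.integer(n_encounters), seed = as.integer(seed),
    frac_septic_physiology = frac_septic_physiology,
    frac_infected_given_flagged = frac_infected_given_flagged,
    frac_infected_background = frac_infected_background,
    frac_secondary_param = frac_secondary_param,
    class_weights = class_weights / sum(class_weights),
    mortality_base_rate = mortality_base_rate,
    mortality_or_per_parameter = mortality_or_per_parameter,
    obs_interval_h = obs_interval_h, update_rate = update_rate,
    los_days_median = los_days_median
  ), class = "cohort_spec")
}

.runif_range <- function(n, lo, hi) lo + (hi - lo) * stats::runif(n)

#' Generate a synthetic cohort with ground truth
#'
#' Builds the four cohort tables plus a per-encounter ground-truth table.
#' Septic-profile encounters contain a deterioration episode: two
#' SIRS-satisfying vital signs followed one hour later by the planted
#' organ-dysfunction value(s), guaranteeing activation of the SEP-2-based
#' screen; control encounters are near-misses (SIRS alone, or one organ
#' criterion alone, never both in conjunction) and are never flagged.
#' Suspected-infection encounters receive a qualifying culture draw and a
#' qualifying intravenous anti-infective; dispositions are drawn from a
#' logistic mortality model over the planted parameter classes. When
#' `update_rate > 0`, corrected lab re-results are planted via
#' [plant_update_noise()] (the correction, not the stale value, is the one
#' consistent with ground truth). Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with elements `cohort` (a
#'   `sepsis_cohort`), `ground_truth` (`data.table` with `encounter_id`,
#'   `septic_profile`, `planted_parameters` (comma-joined), `primary_class`,
#'   `secondary_class`, `infected`, `died_or_hospice`), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_encounters
  eid <- sprintf("E%05d", seq_len(n))

  # --- encounter-level draws -------------------------------------------------
  admit <- floor_minute(as.POSIXct("2016-03-01 00:00", tz = "UTC") +
                          stats::runif(n, 0, 60) * 86400)
  los_h <- exp(stats::rnorm(n, log(spec$los_days_median * 24), 0.55))
  los_h <- pmin(pmax(los_h, 12), 720)
  discharge <- floor_minute(admit + in_hours(los_h))
  los_h <- as.numeric(discharge - admit, units = "hours")
  age <- pmin(pmax(round(stats::rnorm(n, 65, 17)), 18L), 100L)
  sex <- ifelse(stats::runif(n) < 0.48, "female", "male")

  septic <- stats::runif(n) < spec$frac_septic_physiology
  ctrl_type <- ifelse(septic, NA_character_,
                      sample(c("benign", "sirs_only", "organ_only"), n,
                             replace = TRUE, prob = c(0.5, 0.25, 0.25)))
  primary <- rep(NA_character_, n)
  n_sep <- sum(septic)
  if (n_sep) {
    primary[septic] <- sample(names(spec$class_weights), n_sep, replace = TRUE,
                              prob = spec$class_weights)
  }
  # bilirubin plants: a minority exceed the conservative cap
  bili_high <- septic & primary == "bilirubin" & stats::runif(n) < 0.30
  # a second planted parameter for plants invisible to stricter scenarios
  sec_eligible <- septic & (primary %in% c("sbp_drop", "platelets", "inr") |
                              bili_high)
  has_secondary <- sec_eligible & stats::runif(n) < spec$frac_secondary_param
  secondary <- rep(NA_character_, n)
  if (any(has_secondary)) {
    pool <- c("sbp_or_map", "lactate", "creatinine", "bilirubin")
    secondary[has_secondary] <- vapply(
      which(has_secondary),
      function(i) sample(setdiff(pool, primary[i]), 1L), character(1))
  }

  # SBP band per encounter: total in-stay span < 40 mmHg so the drop
  # parameter can only fire where it is planted
  sbp_c <- .runif_range(n, 107, 135)
  sbp_lo <- pmax(92, sbp_c - 15)
  sbp_hi <- sbp_c + 15
  drops <- septic & primary == "sbp_drop"
  sbp_lo[drops] <- 138
  sbp_hi[drops] <- 148

  # deterioration episode time (hours after admission)
  te <- .runif_range(n, 2, pmax(2.5, los_h - 7))

  # --- routine vitals --------------------------------------------------------
  k <- pmax(2L, as.integer(floor(los_h / spec$obs_interval_h)))
  idx <- rep(seq_len(n), k)
  tp <- sequence(k)
  vt_h <- (tp - 1L) * spec$obs_interval_h +
    ifelse(tp == 1L, 0, .runif_range(length(idx), -0.3, 0.3))
  vt_h <- pmin(pmax(vt_h, 0), los_h[idx] - 0.1)
  m <- length(idx)

  temp <- .runif_range(m, 36.2, 38.0)
  hr <- .runif_range(m, 58, 88)
  rr <- .runif_range(m, 11, 19)
  spo2 <- .runif_range(m, 95, 100)
  sbp <- .runif_range(m, sbp_lo[idx], sbp_hi[idx])
  map <- .runif_range(m, 70, 100)

  so <- !is.na(ctrl_type[idx]) & ctrl_type[idx] == "sirs_only"
  temp[so] <- .runif_range(sum(so), 38.5, 39.5)
  hr[so] <- .runif_range(sum(so), 92, 115)
  oo_hr <- !is.na(ctrl_type) & ctrl_type == "organ_only" & stats::runif(n) < 0.5
  hr[oo_hr[idx]] <- .runif_range(sum(oo_hr[idx]), 92, 110)  # one SIRS criterion

  # admission dispersion (feeds the NEWS distribution); respiratory/heart
  # rate dispersion only for controls that can never meet an organ criterion
  adm <- tp == 1L
  spo2_band <- sample(0:3, n, replace = TRUE, prob = c(0.62, 0.15, 0.13, 0.10))
  spo2_adm <- c(.runif_range(n, 96, 100), .runif_range(n, 94, 95.4),
                .runif_range(n, 92, 93.4), .runif_range(n, 88, 91.4))[
                  seq_len(n) + n * spo2_band]
  spo2[adm] <- spo2_adm[idx[adm]]
  disp_ok <- !septic & ctrl_type %in% c("benign", "sirs_only")
  rr_band <- ifelse(disp_ok & stats::runif(n) < 0.35,
                    sample(1:3, n, replace = TRUE, prob = c(0.35, 0.45, 0.20)),
                    0L)
  rr_adm <- c(.runif_range(n, 12, 19), .runif_range(n, 9, 11.4),
              .runif_range(n, 21, 24.4), .runif_range(n, 25, 28))[
                seq_len(n) + n * rr_band]
  rr[adm] <- rr_adm[idx[adm]]

  vitals <- data.table::data.table(
    encounter_id = rep(eid[idx], 6L),
    concept = rep(c("temperature_C", "heart_rate_bpm", "resp_rate_bpm",
                    "spo2_pct", "sbp_mmHg", "map_mmHg"), each = m),
    value = round(c(temp, hr, rr, spo2, sbp, map), 1),
    time_h = rep(vt_h, 6L),
    enc_idx = rep(idx, 6L)
  )

  loc <- ifelse(stats::runif(n) < ifelse(septic, 0.85, 0.92), 0,
                sample(1:3, n, replace = TRUE))
  loc_rows <- data.table::data.table(encounter_id = eid, concept = "loc_avpu",
                                     value = loc, time_h = 0.1,
                                     enc_idx = seq_len(n))

  # --- routine labs ----------------------------------------------------------
  d <- pmax(1L, as.integer(floor(los_h / 24)) + 1L)
  lidx <- rep(seq_len(n), d)
  ld <- sequence(d)
  lt_h <- pmin((ld - 1L) * 24 + .runif_range(length(lidx), 0.3, 1.5),
               los_h[lidx] - 0.05)
  ml <- length(lidx)
  labs <- data.table::data.table(
    encounter_id = rep(eid[lidx], 5L),
    concept = rep(c("wbc_per_mm3", "creatinine_mg_dL", "platelets_per_uL",
                    "bilirubin_mg_dL", "inr"), each = ml),
    value = c(round(.runif_range(ml, 4600, 11500)),
              round(.runif_range(ml, 0.6, 1.5), 2),
              round(.runif_range(ml, 150e3, 380e3)),
              round(.runif_range(ml, 0.3, 1.6), 2),
              round(.runif_range(ml, 0.9, 1.4), 2)),
    time_h = rep(lt_h, 5L),
    enc_idx = rep(lidx, 5L)
  )
  chem <- data.table::data.table(
    encounter_id = rep(eid, 3L),
    concept = rep(c("sodium_mmol_L", "potassium_mmol_L", "chloride_mmol_L"),
                  each = n),
    value = c(round(stats::rnorm(n, 140, 2.5), 1),
              round(stats::rnorm(n, 4.2, 0.35), 1),
              round(stats::rnorm(n, 104, 2.5), 1)),
    time_h = rep(0.7, 3L * n),
    enc_idx = rep(seq_len(n), 3L)
  )
  chem <- chem[chem$value > 0]

  lact_measured <- stats::runif(n) < ifelse(septic, 0.85, 0.30)
  li <- which(lact_measured)
  lact_rows <- data.table::data.table(
    encounter_id = eid[li], concept = "lactate_mmol_L",
    value = round(.runif_range(length(li), 0.6, 1.8), 1),
    time_h = .runif_range(length(li), 1, pmin(8, los_h[li] - 0.2)),
    enc_idx = li
  )

  # --- planted abnormalities -------------------------------------------------
  planted <- list()
  # control organ-only near-misses: one abnormal organ value, never >=2 SIRS
  oo <- which(!septic & ctrl_type == "organ_only")
  if (length(oo)) {
    oc <- sample(c("lactate_mmol_L", "bilirubin_mg_dL", "platelets_per_uL"),
                 length(oo), replace = TRUE)
    ov <- ifelse(oc == "lactate_mmol_L",
                 round(.runif_range(length(oo), 2.2, 3.5), 1),
          ifelse(oc == "bilirubin_mg_dL",
                 round(.runif_range(length(oo), 2.2, 4.0), 2),
                 round(.runif_range(length(oo), 60e3, 90e3))))
    planted$organ_only <- data.table::data.table(
      encounter_id = eid[oo], concept = oc, value = ov,
      time_h = .runif_range(length(oo), 2, los_h[oo] - 1), enc_idx = oo)
  }

  sep_i <- which(septic)
  if (length(sep_i)) {
    planted$episode_sirs <- data.table::data.table(
      encounter_id = rep(eid[sep_i], 2L),
      concept = rep(c("temperature_C", "heart_rate_bpm"), each = length(sep_i)),
      value = round(c(.runif_range(length(sep_i), 38.8, 39.8),
                      .runif_range(length(sep_i), 100, 125)), 1),
      time_h = rep(te[sep_i], 2L),
      enc_idx = rep(sep_i, 2L)
    )
    plant_class_rows <- function(i, class, at_h) {
      cls_concept <- c(sbp_drop = "sbp_mmHg", sbp_or_map = "map_mmHg",
                       lactate = "lactate_mmol_L",
                       bilirubin = "bilirubin_mg_dL",
                       creatinine = "creatinine_mg_dL",
                       platelets = "platelets_per_uL", inr = "inr")
      val <- vapply(seq_along(i), function(j) {
        switch(class[j],
          sbp_drop = round(.runif_range(1, 92.5, 96), 1),
          sbp_or_map = round(.runif_range(1, 55, 62), 1),
          lactate = round(.runif_range(1, 2.6, 6), 1),
          bilirubin = if (bili_high[i[j]]) round(.runif_range(1, 10.5, 14), 1)
                      else round(.runif_range(1, 2.5, 8), 2),
          creatinine = round(.runif_range(1, 2.3, 4), 2),
          platelets = round(.runif_range(1, 40e3, 90e3)),
          inr = round(.runif_range(1, 1.8, 3), 2))
      }, numeric(1))
      data.table::data.table(encounter_id = eid[i],
                             concept = cls_concept[class], value = val,
                             time_h = at_h, enc_idx = i)
    }
    single <- sep_i[primary[sep_i] != "mods"]
    if (length(single)) {
      planted$primary <- plant_class_rows(single, primary[single],
                                          te[single] + 1)
    }
    mods_i <- sep_i[primary[sep_i] == "mods"]
    if (length(mods_i)) {
      planted$mods <- rbind(
        plant_class_rows(mods_i, rep("lactate", length(mods_i)),
                         te[mods_i] + 1),
        plant_class_rows(mods_i, rep("creatinine", length(mods_i)),
                         te[mods_i] + 1))
    }
    sec_i <- which(has_secondary)
    if (length(sec_i)) {
      # secondary bilirubin plants stay below the conservative cap
      bh <- bili_high
      bili_high[sec_i] <- FALSE
      planted$secondary <- plant_class_rows(sec_i, secondary[sec_i],
                                            te[sec_i] + 7)
      bili_high <- bh
    }
  }

  obs <- data.table::rbindlist(c(list(vitals, loc_rows, labs, chem, lact_rows),
                                 planted), use.names = TRUE)
  obs[, `:=`(event_time = floor_minute(admit[enc_idx] + in_hours(time_h)),
             update_seq = 0L)]
  obs[, c("time_h", "enc_idx") := NULL]
  obs <- .separate_colliding_events(obs)

  # --- infection -------------------------------------------------------------
  p_inf_class <- .CLASS_INFECTION_REL *
    (spec$frac_infected_given_flagged /
       sum(spec$class_weights * .CLASS_INFECTION_REL[names(spec$class_weights)]))
  p_inf_class <- pmin(p_inf_class, 1)
  p_inf <- ifelse(septic, p_inf_class[primary], spec$frac_infected_background)
  infected <- stats::runif(n) < p_inf

  inf_i <- which(infected)
  cul_t <- ifelse(septic[inf_i], te[inf_i] + .runif_range(length(inf_i), -1, 2),
                  .runif_range(length(inf_i), 1, pmax(1.5, los_h[inf_i] - 4)))
  cul_t <- pmin(pmax(cul_t, 0.2), los_h[inf_i] - 0.5)
  cultures <- data.table::data.table(
    encounter_id = eid[inf_i],
    specimen = sample(qualifying_specimens(), length(inf_i), replace = TRUE),
    collect_time = floor_minute(admit[inf_i] + in_hours(cul_t))
  )
  med_admins <- data.table::data.table(
    encounter_id = eid[inf_i],
    drug = sample(qualifying_antibiotics(), length(inf_i), replace = TRUE),
    route = "IV",
    admin_time = floor_minute(admit[inf_i] +
                                in_hours(pmin(cul_t + 2, los_h[inf_i] - 0.2)))
  )
  # non-qualifying noise: oral antibiotics, unlisted IV drugs, and
  # culture-only / antibiotic-only encounters that must NOT label as infected
  safe_sample <- function(pool, size) {
    pool[sample.int(length(pool), min(size, length(pool)))]
  }
  not_inf <- which(!infected)
  po <- safe_sample(not_inf, round(0.08 * length(not_inf)))
  iv_other <- safe_sample(setdiff(not_inf, po), round(0.05 * length(not_inf)))
  cul_only <- safe_sample(setdiff(not_inf, c(po, iv_other)),
                          round(0.08 * length(not_inf)))
  med_admins <- rbind(
    med_admins,
    data.table::data.table(encounter_id = eid[po], drug = "ciprofloxacin",
                           route = "PO",
                           admin_time = floor_minute(admit[po] + in_hours(3))),
    data.table::data.table(encounter_id = eid[iv_other], drug = "ondansetron",
                           route = "IV",
                           admin_time = floor_minute(admit[iv_other] +
                                                       in_hours(2))))
  cultures <- rbind(
    cultures,
    data.table::data.table(
      encounter_id = eid[cul_only],
      specimen = sample(qualifying_specimens(), length(cul_only),
                        replace = TRUE),
      collect_time = floor_minute(admit[cul_only] + in_hours(2))))

  # --- mortality -------------------------------------------------------------
  planted_params <- lapply(seq_len(n), function(i) {
    if (!septic[i]) return(character())
    pp <- if (primary[i] == "mods") c("lactate", "creatinine") else primary[i]
    if (!is.na(secondary[i])) pp <- c(pp, secondary[i])
    unique(pp)
  })
  or_map <- spec$mortality_or_per_parameter
  lo <- stats::qlogis(spec$mortality_base_rate) +
    vapply(planted_params, function(pp) {
      if (!length(pp)) 0 else sum(log(or_map[pp]))
    }, numeric(1))
  died <- stats::runif(n) < stats::plogis(lo)
  disposition <- ifelse(died,
                        ifelse(stats::runif(n) < 0.75, "expired", "hospice"),
                        "home_or_other")
  icu <- stats::runif(n) < ifelse(septic, 0.45, 0.12)

  encounters <- data.table::data.table(
    encounter_id = eid, age_years = age, sex = sex, admit_time = admit,
    discharge_time = discharge, disposition = disposition,
    icu_within_48h = icu)

  ground_truth <- data.table::data.table(
    encounter_id = eid,
    septic_profile = septic,
    planted_parameters = vapply(planted_params, paste, character(1),
                                collapse = ","),
    primary_class = primary,
    secondary_class = secondary,
    infected = infected,
    died_or_hospice = died
  )

  cohort <- as_cohort(encounters, obs, cultures, med_admins, quiet = TRUE)
  out <- structure(list(cohort = cohort, ground_truth = ground_truth,
                        spec = spec), class = "synthetic_cohort")
  if (spec$update_rate > 0) {
    out <- plant_update_noise(out, spec)
  }
  out
}

# minute-resolution collisions between a planted row and a routine row of
# the same concept would look like a tied correction counter; nudge the
# later row forward one minute until every (encounter, concept, time) is a
# distinct clinical event
.separate_colliding_events <- function(obs) {
  key <- c("encounter_id", "concept", "event_time")
  data.table::setorderv(obs, key)
  repeat {
    dup <- duplicated(obs, by = key)
    if (!any(dup)) break
    obs$event_time[dup] <- obs$event_time[dup] + 60
    data.table::setorderv(obs, key)
  }
  obs
}

#' Plant corrected lab re-results
#'
#' For a fraction `spec$update_rate` of laboratory events, rewrites the
#' original instance (`update_seq = 0`) to a perturbed stale value and
#' appends the true value as a correction with `update_seq = 1`. After
#' [resolve_timeline()] the corrected value — the one consistent with ground
#' truth — is the one seen by every downstream stage, so screening results
#' on noised and clean tables are identical. Uses the current RNG state
#' (seeded when called from [generate_cohort()]).
#'
#' @param x A `synthetic_cohort` or a `sepsis_cohort`.
#' @param spec A [cohort_spec()]; only `update_rate` is used.
#' @return Object of the same class with the noised observation table.
#' @export
plant_update_noise <- function(x, spec) {
  cohort <- if (inherits(x, "synthetic_cohort")) x$cohort else x
  stopifnot(inherits(cohort, "sepsis_cohort"))
  rate <- spec$update_rate
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  obs <- data.table::copy(cohort$observations)
  lab <- which(obs$concept %in% .lab_concepts() & obs$update_seq == 0L)
  pick <- lab[stats::runif(length(lab)) < rate]
  if (length(pick)) {
    reg <- .CONCEPTS[match(obs$concept[pick], .CONCEPTS$concept)]
    corrected <- obs[pick]
    corrected[, update_seq := 1L]
    stale <- obs$value[pick] * .runif_range(length(pick), 0.75, 1.25)
    obs$value[pick] <- pmin(pmax(stale, reg$lower), reg$upper)
    obs <- rbind(obs, corrected)
    data.table::setorderv(obs, c("encounter_id", "concept", "event_time",
                                 "update_seq"))
  }
  cohort$observations <- obs[]
  if (inherits(x, "synthetic_cohort")) {
    x$cohort <- cohort
    x
  } else {
    cohort
  }
}

#' Write a synthetic cohort to disk
#'
#' Emits the four cohort tables via [write_cohort()] plus `ground_truth.csv`
#' and the generating specification echoed to `spec.yaml`.
#'
#' @param x A `synthetic_cohort`.
#' @param path Output directory.
#' @param dialect Passed to [write_cohort()].
#' @return `path`, invisibly.
#' @export
write_synthetic_cohort <- function(x, path, dialect = "csv") {
  stopifnot(inherits(x, "synthetic_cohort"))
  write_cohort(x$cohort, path, dialect = dialect)
  data.table::fwrite(x$ground_truth, file.path(path, "ground_truth.csv"))
  sp <- unclass(x$spec)
  sp$class_weights <- as.list(sp$class_weights)
  sp$mortality_or_per_parameter <- as.list(sp$mortality_or_per_parameter)
  yaml::write_yaml(sp, file.path(path, "spec.yaml"))
  invisible(path)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$ground_truth), "encounters,",
      sum(x$ground_truth$septic_profile), "septic profiles,",
      sum(x$ground_truth$infected), "infected\n")
  invisible(x)
}
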