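# Temporal rules engine. Criteria are evaluated at every observation event
# time (alert state can only change when data arrive); each criterion looks
# back over its own half-open trailing window (t - lookback, t].

.SIRS_CRITERIA <- c("temperature", "heart_rate", "resp_rate", "wbc")
.ORGAN_PARAMS <- c("sbp_drop", "sbp_or_map", "lactate", "bilirubin",
                   "creatinine", "platelets", "inr")
.ORGAN_SYSTEM <- c(sbp_drop = "cardiovascular", sbp_or_map = "cardiovascular",
                   lactate = "cardiovascular", bilirubin = "hepatic",
                   creatinine = "renal", platelets = "hematologic",
                   inr = "hematologic")
# within-system attribution precedence follows the order in which the
# criteria are enumerated in the screen definition
.ATTRIBUTION_ORDER <- c("sbp_drop", "sbp_or_map", "lactate", "bilirubin",
                        "creatinine", "platelets", "inr")
.ALERT_CLASSES <- c("sbp_drop", "sbp_or_map", "lactate", "bilirubin",
                    "creatinine", "mods", "platelets", "inr")

#' Attribution classes and organ systems
#'
#' The mutually exclusive classes a flagged encounter can be attributed to:
#' the seven organ-dysfunction parameters plus `mods` (criteria from two or
#' more distinct organ systems met at alert time). Systems: cardiovascular =
#' {sbp_drop, sbp_or_map, lactate}, hepatic = {bilirubin}, renal =
#' {creatinine}, hematologic = {platelets, inr}.
#'
#' @return `alert_classes()`: character vector of the eight classes.
#'   `organ_systems()`: named character vector mapping parameter to system.
#' @export
alert_classes <- function() .ALERT_CLASSES

#' @rdname alert_classes
#' @export
organ_systems <- function() .ORGAN_SYSTEM

# --- window primitives -------------------------------------------------------

# For each evaluation time, is there a qualifying observation time in the
# half-open window (t - lookback_s, t]? qual_times must be sorted ascending.
.met_in_window <- function(eval_times, qual_times, lookback_s) {
  if (!length(qual_times)) return(rep(FALSE, length(eval_times)))
  idx <- findInterval(eval_times, qual_times)
  idx > 0L & qual_times[pmax(idx, 1L)] > eval_times - lookback_s
}

# Split a resolved timeline into per-concept numeric time/value vectors.
.tl_split <- function(timeline) {
  out <- split(
    data.frame(t = as.numeric(timeline$event_time), v = timeline$value),
    timeline$concept
  )
  lapply(out, function(d) d[order(d$t), , drop = FALSE])
}

.concept_times <- function(parts, concept, qualifies) {
  d <- parts[[concept]]
  if (is.null(d)) return(numeric())
  d$t[qualifies(d$v)]
}

# --- criteria evaluation over a vector of instants ---------------------------

.sirs_matrix <- function(parts, eval_times, config) {
  s <- config$sirs
  lb <- in_hours(config$lookback_default_h)
  wbc_times <- sort(c(
    .concept_times(parts, "wbc_per_mm3",
                   function(v) v > s$wbc_high_per_mm3 | v < s$wbc_low_per_mm3),
    .concept_times(parts, "band_pct", function(v) v > s$band_high_pct)
  ))
  cbind(
    temperature = .met_in_window(
      eval_times,
      .concept_times(parts, "temperature_C",
                     function(v) v > s$temp_high_C | v < s$temp_low_C), lb),
    heart_rate = .met_in_window(
      eval_times,
      .concept_times(parts, "heart_rate_bpm", function(v) v > s$hr_high_bpm),
      lb),
    resp_rate = .met_in_window(
      eval_times,
      .concept_times(parts, "resp_rate_bpm", function(v) v > s$rr_high_bpm),
      lb),
    wbc = .met_in_window(eval_times, wbc_times, lb)
  )
}

.organ_matrix <- function(parts, eval_times, config) {
  lb30 <- in_hours(config$lookback_default_h)
  n <- length(eval_times)

  sbp_or_map <- .met_in_window(
    eval_times,
    sort(c(.concept_times(parts, "sbp_mmHg",
                          function(v) v < config$sbp_low_mmHg),
           .concept_times(parts, "map_mmHg",
                          function(v) v < config$map_low_mmHg))), lb30)

  lactate <- .met_in_window(
    eval_times,
    .concept_times(parts, "lactate_mmol_L",
                   function(v) v > config$lactate_high_mmol_L),
    in_hours(config$lookback_lactate_h))

  bil_qual <- function(v) {
    ok <- v >= config$bilirubin_low_mg_dL
    if (!is.null(config$bilirubin_cap_mg_dL)) {
      ok <- ok & v <= config$bilirubin_cap_mg_dL
    }
    ok
  }
  bilirubin <- .met_in_window(
    eval_times, .concept_times(parts, "bilirubin_mg_dL", bil_qual), lb30)

  creatinine <- .creatinine_met(parts, eval_times, config)

  if (config$platelets_inr_enabled) {
    platelets <- .met_in_window(
      eval_times,
      .concept_times(parts, "platelets_per_uL",
                     function(v) v < config$platelets_low_per_uL), lb30)
    inr <- .met_in_window(
      eval_times,
      .concept_times(parts, "inr", function(v) v > config$inr_high), lb30)
  } else {
    platelets <- inr <- rep(FALSE, n)
  }

  sbp_drop <- if (config$sbp_drop_enabled) {
    .sbp_drop_met(parts, eval_times, config)
  } else {
    rep(FALSE, n)
  }

  cbind(sbp_drop = sbp_drop, sbp_or_map = sbp_or_map, lactate = lactate,
        bilirubin = bilirubin, creatinine = creatinine,
        platelets = platelets, inr = inr)
}

# SBP decrease from baseline: baseline is the FIRST SBP reading inside the
# default lookback window; the parameter is met when baseline minus the
# window minimum strictly exceeds the drop threshold.
.sbp_drop_met <- function(parts, eval_times, config) {
  d <- parts[["sbp_mmHg"]]
  n <- length(eval_times)
  if (is.null(d) || nrow(d) < 2L) return(rep(FALSE, n))
  lb <- in_hours(config$lookback_default_h)
  lo <- findInterval(eval_times - lb, d$t)  # readings at exactly t-lb excluded
  hi <- findInterval(eval_times, d$t)
  met <- logical(n)
  for (i in seq_len(n)) {
    if (hi[i] > lo[i] + 1L) {  # need baseline plus at least one later reading
      w <- d$v[(lo[i] + 1L):hi[i]]
      met[i] <- (w[1L] - min(w)) > config$sbp_drop_mmHg
    }
  }
  met
}

# Creatinine: >= threshold within the creatinine lookback; when the delta
# rule is active the qualifying high value must additionally represent a rise
# of at least delta from the window minimum observed up to that value.
.creatinine_met <- function(parts, eval_times, config) {
  d <- parts[["creatinine_mg_dL"]]
  n <- length(eval_times)
  if (is.null(d)) return(rep(FALSE, n))
  lb <- in_hours(config$lookback_creatinine_h)
  if (!config$creatinine_delta_required) {
    return(.met_in_window(eval_times,
                          d$t[d$v >= config$creatinine_high_mg_dL], lb))
  }
  lo <- findInterval(eval_times - lb, d$t)
  hi <- findInterval(eval_times, d$t)
  met <- logical(n)
  for (i in seq_len(n)) {
    if (hi[i] > lo[i]) {
      w <- d$v[(lo[i] + 1L):hi[i]]
      met[i] <- any(w >= config$creatinine_high_mg_dL &
                      (w - cummin(w)) >= config$creatinine_delta_mg_dL)
    }
  }
  met
}

# --- public single-instant operations ---------------------------------------

#' Evaluate the SIRS criteria at one instant
#'
#' A criterion is met when any observation of its concept inside the default
#' lookback window crosses its threshold. All SIRS thresholds are strict
#' inequalities; the WBC criterion is met by a high count, a low count, or
#' band forms above 10%. Absent data mean the criterion is not met.
#'
#' @param timeline A [resolve_timeline()] result.
#' @param at Evaluation timestamp.
#' @param config A [scenario_config()].
#' @return Character vector, a subset of
#'   `c("temperature", "heart_rate", "resp_rate", "wbc")`.
#' @export
eval_sirs <- function(timeline, at, config = scenario_preset("sep2_based")) {
  at <- as.numeric(parse_clinical_time(at))
  m <- .sirs_matrix(.tl_split(timeline), at, config)
  colnames(m)[m[1L, ]]
}

#' Evaluate the organ-dysfunction parameters at one instant
#'
#' @inheritParams eval_sirs
#' @return Character vector, a subset of the parameter names in
#'   [organ_systems()]. Parameters disabled by the scenario are never
#'   returned.
#' @export
eval_organ_dysfunction <- function(timeline, at,
                                   config = scenario_preset("sep2_based")) {
  at <- as.numeric(parse_clinical_time(at))
  m <- .organ_matrix(.tl_split(timeline), at, config)
  colnames(m)[m[1L, ]]
}

#' Baseline systolic blood pressure
#'
#' The first SBP reading within the default lookback window ending at `at`;
#' this is the reference value for the SBP-decrease parameter.
#'
#' @inheritParams eval_sirs
#' @param lookback_h Window length in hours (default 30).
#' @return The baseline SBP in mmHg, or `NA` when no reading is in window.
#' @export
baseline_sbp <- function(timeline, at, lookback_h = 30) {
  w <- window_values(timeline, "sbp_mmHg", at, lookback_h)
  if (nrow(w) == 0L) NA_real_ else w$value[1L]
}

#' Attribute a flagged encounter to a single parameter class
#'
#' Implements the mutually exclusive attribution used in per-parameter
#' reporting: when the parameters met at alert time span two or more organ
#' systems the class is `mods`; within a single system the class is resolved
#' by precedence in the order the criteria are defined (cardiovascular:
#' sbp_drop > sbp_or_map > lactate; hematologic: platelets > inr).
#'
#' @param organ_parameters_met Nonempty character vector of parameters met.
#' @return A single class name, see [alert_classes()].
#' @export
#' @examples
#' attribute_class(c("lactate", "creatinine"))   # two systems -> "mods"
#' attribute_class(c("sbp_drop", "lactate"))     # one system  -> "sbp_drop"
attribute_class <- function(organ_parameters_met) {
  if (length(organ_parameters_met) == 0L) {
    stop("cannot attribute an empty parameter set", call. = FALSE)
  }
  bad <- setdiff(organ_parameters_met, .ORGAN_PARAMS)
  if (length(bad)) {
    stop("unknown organ parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  systems <- unique(.ORGAN_SYSTEM[organ_parameters_met])
  if (length(systems) >= 2L) return("mods")
  .ATTRIBUTION_ORDER[.ATTRIBUTION_ORDER %in% organ_parameters_met][1L]
}

# --- encounter / cohort screening -------------------------------------------

#' Screen one encounter for severe sepsis
#'
#' Runs the screen at every observation event time from admission to
#' discharge. The encounter is flagged at the first instant at which at
#' least two SIRS criteria and at least one organ-dysfunction parameter are
#' simultaneously satisfied (each criterion judged over its own lookback
#' window); the criteria sets and the attributed class are recorded as of
#' that first activation.
#'
#' @param encounter One-row encounter record (needs `encounter_id`,
#'   `admit_time`, `discharge_time`).
#' @param timeline The encounter's [resolve_timeline()] result.
#' @param config A [scenario_config()].
#' @return An `alert_result` list: `encounter_id`, `flagged`,
#'   `first_alert_time` (`NA` when never flagged), `sirs_criteria_met`,
#'   `organ_parameters_met`, `attributed_class` (`NA` when not flagged).
#' @export
screen_encounter <- function(encounter, timeline,
                             config = scenario_preset("sep2_based")) {
  admit <- parse_clinical_time(encounter$admit_time)
  discharge <- parse_clinical_time(encounter$discharge_time)
  if (is.na(admit) || is.na(discharge) || discharge <= admit) {
    stop("encounter ", encounter$encounter_id,
         ": discharge_time must be after admit_time", call. = FALSE)
  }
  eval_times <- sort(unique(as.numeric(timeline$event_time)))
  eval_times <- eval_times[eval_times >= as.numeric(admit) &
                             eval_times <= as.numeric(discharge)]
  res <- .screen_at_times(.tl_split(timeline), eval_times, config)
  res$encounter_id <- as.character(encounter$encounter_id)
  structure(res[c("encounter_id", "flagged", "first_alert_time",
                  "sirs_criteria_met", "organ_parameters_met",
                  "attributed_class")],
            class = "alert_result")
}

.screen_at_times <- function(parts, eval_times, config) {
  if (length(eval_times)) {
    sirs <- .sirs_matrix(parts, eval_times, config)
    organ <- .organ_matrix(parts, eval_times, config)
    hit <- which(rowSums(sirs) >= 2L & rowSums(organ) >= 1L)
  } else {
    hit <- integer()
  }
  if (length(hit)) {
    i <- hit[1L]
    organ_met <- colnames(organ)[organ[i, ]]
    list(flagged = TRUE,
         first_alert_time = as.POSIXct(eval_times[i], origin = "1970-01-01",
                                       tz = "UTC"),
         sirs_criteria_met = colnames(sirs)[sirs[i, ]],
         organ_parameters_met = organ_met,
         attributed_class = attribute_class(organ_met))
  } else {
    list(flagged = FALSE,
         first_alert_time = as.POSIXct(NA, tz = "UTC"),
         sirs_criteria_met = character(),
         organ_parameters_met = character(),
         attributed_class = NA_character_)
  }
}

#' Screen every encounter in a cohort
#'
#' Resolves each encounter's event stream (collapsing corrected re-results)
#' and applies [screen_encounter()] under one scenario.
#'
#' @param cohort A `sepsis_cohort`.
#' @param config A [scenario_config()].
#' @return A `data.table` with one row per encounter: `encounter_id`,
#'   `flagged`, `first_alert_time`, `sirs_met` and `organ_met`
#'   (comma-joined), `attributed_class`, plus the scenario name as attribute
#'   `scenario`.
#' @export
screen_cohort <- function(cohort, config = scenario_preset("sep2_based")) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  obs <- cohort$observations
  # vectorized update resolution across the whole cohort
  key <- c("encounter_id", "concept", "event_time")
  data.table::setorderv(obs, c(key, "update_seq"))
  resolved <- obs[obs[, .I[.N], by = key]$V1]
  parts_by_enc <- split(resolved, by = "encounter_id", keep.by = FALSE)

  enc <- cohort$encounters
  out <- vector("list", nrow(enc))
  for (i in seq_len(nrow(enc))) {
    eid <- enc$encounter_id[i]
    tl <- parts_by_enc[[eid]]
    if (is.null(tl)) {
      eval_times <- numeric()
      parts <- list()
    } else {
      eval_times <- sort(unique(as.numeric(tl$event_time)))
      eval_times <- eval_times[eval_times >= as.numeric(enc$admit_time[i]) &
                                 eval_times <= as.numeric(enc$discharge_time[i])]
      parts <- .tl_split(tl)
    }
    r <- .screen_at_times(parts, eval_times, config)
    out[[i]] <- data.table::data.table(
      encounter_id = eid,
      flagged = r$flagged,
      first_alert_time = r$first_alert_time,
      sirs_met = paste(r$sirs_criteria_met, collapse = ","),
      organ_met = paste(r$organ_parameters_met, collapse = ","),
      attributed_class = r$attributed_class
    )
  }
  alerts <- data.table::rbindlist(out)
  data.table::setattr(alerts, "scenario", config$name)
  alerts[]
}

#' @export
print.alert_result <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("<alert_result> %s FLAGGED at %s [%s] sirs={%s} organ={%s}\n",
                x$encounter_id, format_clinical_time(x$first_alert_time),
                x$attributed_class,
                paste(x$sirs_criteria_met, collapse = ","),
                paste(x$organ_parameters_met, collapse = ",")))
  } else {
    cat(sprintf("<alert_result> %s not flagged\n", x$encounter_id))
  }
  invisible(x)
}
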