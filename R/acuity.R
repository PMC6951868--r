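# Admission-time acuity: the six-component NEWS composite (no supplemental
# oxygen item, hence a 0-18 point range) and the apparent strong ion
# difference (SIDa) flag for severe electrolyte/metabolic disturbance.

.NEWS_CATEGORIES <- c("0-4", "5-6", "7-8", "9-25")

.news_rr <- function(v) {
  ifelse(is.na(v), 0L,
  ifelse(v <= 8, 3L, ifelse(v <= 11, 1L, ifelse(v <= 20, 0L,
  ifelse(v <= 24, 2L, 3L)))))
}
.news_spo2 <- function(v) {
  ifelse(is.na(v), 0L,
  ifelse(v <= 91, 3L, ifelse(v <= 93, 2L, ifelse(v <= 95, 1L, 0L))))
}
.news_temp <- function(v) {
  ifelse(is.na(v), 0L,
  ifelse(v <= 35.0, 3L, ifelse(v <= 36.0, 1L, ifelse(v <= 38.0, 0L,
  ifelse(v <= 39.0, 1L, 2L)))))
}
.news_sbp <- function(v) {
  ifelse(is.na(v), 0L,
  ifelse(v <= 90, 3L, ifelse(v <= 100, 2L, ifelse(v <= 110, 1L,
  ifelse(v <= 219, 0L, 3L)))))
}
.news_hr <- function(v) {
  ifelse(is.na(v), 0L,
  ifelse(v <= 40, 3L, ifelse(v <= 50, 1L, ifelse(v <= 90, 0L,
  ifelse(v <= 110, 1L, ifelse(v <= 130, 2L, 3L))))))
}
.news_loc <- function(v) ifelse(is.na(v) | v == 0, 0L, 3L)  # A=0; V/P/U -> 3

#' NEWS composite acuity score (six-component variant)
#'
#' Sums the standard NEWS subscores for respiratory rate, oxygen saturation,
#' temperature, systolic blood pressure, heart rate and level of
#' consciousness (AVPU, encoded A=0/V=1/P=2/U=3). The supplemental-oxygen
#' item is not part of this variant, so the maximum is 18 points. Missing
#' components contribute 0 points with a warning rather than excluding the
#' patient. Vectorized over patients.
#'
#' @param resp_rate,spo2,temperature,sbp,heart_rate,loc Numeric vectors of
#'   the first documented post-admission value per component.
#' @return A `data.table` with `news_points` (0-18) and `news_category`
#'   (bands `0-4`, `5-6`, `7-8`, `9-25`).
#' @export
#' @examples
#' news_score(16, 97, 37.0, 120, 70, 0)   # all normal: 0 points
#' news_score(26, 90, 35.0, 85, 135, 3)   # every component maximal: 18
news_score <- function(resp_rate, spo2, temperature, sbp, heart_rate, loc) {
  args <- list(resp_rate, spo2, temperature, sbp, heart_rate, loc)
  if (any(vapply(args, anyNA, logical(1)))) {
    warning("missing NEWS component(s) scored as 0 points", call. = FALSE)
  }
  points <- .news_rr(resp_rate) + .news_spo2(spo2) + .news_temp(temperature) +
    .news_sbp(sbp) + .news_hr(heart_rate) + .news_loc(loc)
  data.table::data.table(news_points = points,
                         news_category = news_category(points))
}

#' @rdname news_score
#' @param points Integer NEWS points.
#' @return `news_category()`: factor with the four bands as levels.
#' @export
news_category <- function(points) {
  cut(points, breaks = c(-1, 4, 6, 8, 25), labels = .NEWS_CATEGORIES)
}

#' Apparent strong ion difference
#'
#' Corrected SIDa = (Na + K + 1.85) - Cl, in mmol/L, computed from the first
#' clinical chemistry results. Values at or below 34.0 or at or above 48.0
#' mmol/L are flagged as severe electrolyte/metabolic disturbance (both
#' boundaries inclusive).
#'
#' @param sodium,potassium,chloride Analyte concentrations in mmol/L; must be
#'   finite.
#' @return A `data.table` with `sida` and `sida_flag`.
#' @export
#' @examples
#' sida(140, 4.0, 104)   # 41.85, not flagged
#' sida(130, 3.0, 105)   # 29.85, flagged low
sida <- function(sodium, potassium, chloride) {
  if (any(!is.finite(sodium)) || any(!is.finite(potassium)) ||
      any(!is.finite(chloride))) {
    stop("sida() requires finite analyte values", call. = FALSE)
  }
  value <- sodium + potassium + 1.85 - chloride
  data.table::data.table(sida = value,
                         sida_flag = value <= 34.0 | value >= 48.0)
}

#' Admission acuity profile for every encounter in a cohort
#'
#' For each encounter, selects the first documented post-admission value of
#' each NEWS component independently (components may come from different
#' instants) and the first sodium/potassium/chloride results, then computes
#' [news_score()] and [sida()]. When any of the three SIDa analytes is never
#' measured the SIDa value is `NA` and the flag is `FALSE`.
#'
#' @param cohort A `sepsis_cohort`.
#' @return A `data.table`: `encounter_id`, `news_points`, `news_category`,
#'   `sida`, `sida_flag`.
#' @export
acuity_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  need <- c(rr = "resp_rate_bpm", spo2 = "spo2_pct", temp = "temperature_C",
            sbp = "sbp_mmHg", hr = "heart_rate_bpm", loc = "loc_avpu",
            na = "sodium_mmol_L", k = "potassium_mmol_L",
            cl = "chloride_mmol_L")
  obs <- merge(
    cohort$observations[cohort$observations$concept %in% need],
    cohort$encounters[, c("encounter_id", "admit_time")],
    by = "encounter_id"
  )
  obs <- obs[obs$event_time >= obs$admit_time]
  key <- c("encounter_id", "concept", "event_time")
  data.table::setorderv(obs, c(key, "update_seq"))
  obs <- obs[obs[, .I[.N], by = key]$V1]  # resolve corrections
  data.table::setorderv(obs, c("encounter_id", "concept", "event_time"))
  encounter_id <- concept <- value <- NULL
  first <- obs[, .(value = value[1L]), by = .(encounter_id, concept)]
  wide <- data.table::dcast(first, encounter_id ~ concept,
                            value.var = "value")
  for (cc in need) {
    if (!cc %in% names(wide)) wide[, (cc) := NA_real_]
  }
  wide <- merge(cohort$encounters[, "encounter_id"], wide,
                by = "encounter_id", all.x = TRUE)
  ns <- suppressWarnings(news_score(
    wide$resp_rate_bpm, wide$spo2_pct, wide$temperature_C, wide$sbp_mmHg,
    wide$heart_rate_bpm, wide$loc_avpu
  ))
  out <- data.table::data.table(encounter_id = wide$encounter_id, ns)
  have_chem <- is.finite(wide$sodium_mmol_L) &
    is.finite(wide$potassium_mmol_L) & is.finite(wide$chloride_mmol_L)
  out[, `:=`(sida = NA_real_, sida_flag = FALSE)]
  if (any(have_chem)) {
    sd <- sida(wide$sodium_mmol_L[have_chem], wide$potassium_mmol_L[have_chem],
               wide$chloride_mmol_L[have_chem])
    out$sida[have_chem] <- sd$sida
    out$sida_flag[have_chem] <- sd$sida_flag
  }
  out[]
}
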