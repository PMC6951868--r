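# Event store: observation events with an update counter, resolved into a
# per-encounter timeline in which each clinical event (concept, event_time)
# is represented exactly once by its latest correction.

#' Construct a table of observation events
#'
#' Light constructor for in-memory event tables. Each row is one timestamped
#' clinical measurement; `update_seq` is the correction counter: when the
#' same clinical event (same encounter, concept and event time) is re-resulted,
#' the later instance carries a higher `update_seq` and supersedes the earlier
#' one at resolution.
#'
#' @param encounter_id Character vector.
#' @param concept Concept codes, see [concept_registry()].
#' @param value Numeric measurement values.
#' @param event_time Timestamps (`POSIXct` or parseable character).
#' @param update_seq Non-negative integer correction counter (default 0).
#' @return A `data.table` of class `observation_events`.
#' @export
observation_events <- function(encounter_id, concept, value, event_time,
                               update_seq = 0L) {
  .assert_concept(concept)
  ev <- data.table::data.table(
    encounter_id = as.character(encounter_id),
    concept = as.character(concept),
    value = as.numeric(value),
    event_time = parse_clinical_time(event_time),
    update_seq = as.integer(update_seq)
  )
  if (anyNA(ev$event_time)) stop("unparseable event_time", call. = FALSE)
  if (any(!is.finite(ev$value))) stop("non-finite value", call. = FALSE)
  if (any(ev$update_seq < 0L)) stop("negative update_seq", call. = FALSE)
  data.table::setattr(ev, "class", c("observation_events", class(ev)))
  ev[]
}

#' Resolve an encounter's event stream into a timeline
#'
#' Collapses corrected re-results: within each (concept, event_time) group —
#' one clinical event — only the instance with the highest `update_seq`
#' survives. The result is sorted ascending by event time within concept, and
#' is invariant to the input order of the events.
#'
#' @param events A table of observation events for a single encounter
#'   (columns `encounter_id`, `concept`, `value`, `event_time`, `update_seq`).
#' @return A `resolved_timeline`: a `data.table` with columns `concept`,
#'   `event_time`, `value`, sorted by (`concept`, `event_time`), carrying the
#'   encounter id as attribute `encounter_id`. Empty input yields an empty
#'   timeline.
#' @details Ties among equal `update_seq` values for one clinical event are a
#'   data error (the counter exists precisely to disambiguate) and raise an
#'   error; ingest via [read_cohort()] rejects such rows up front.
#' @export
#' @examples
#' ev <- observation_events("E1", "lactate_mmol_L", c(3.1, 2.0),
#'                          rep("2016-03-01 10:00", 2), update_seq = c(0, 1))
#' resolve_timeline(ev)  # only the corrected 2.0 survives
resolve_timeline <- function(events) {
  events <- data.table::as.data.table(events)
  eid <- unique(events$encounter_id)
  if (length(eid) > 1L) {
    stop("events span multiple encounters: ", paste(eid, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) == 0L) {
    tl <- data.table::data.table(concept = character(),
                                 event_time = parse_clinical_time(character()),
                                 value = numeric())
    data.table::setattr(tl, "encounter_id", NA_character_)
    data.table::setattr(tl, "class", c("resolved_timeline", class(tl)))
    return(tl)
  }
  concept <- event_time <- update_seq <- NULL # data.table NSE
  dup <- anyDuplicated(events, by = c("concept", "event_time", "update_seq"))
  if (dup) {
    stop("tied update_seq for the same clinical event; ",
         "corrections must carry distinct counters", call. = FALSE)
  }
  data.table::setorder(events, concept, event_time, update_seq)
  tl <- events[events[, .I[.N], by = .(concept, event_time)]$V1,
               .(concept, event_time, value)]
  data.table::setorder(tl, concept, event_time)
  data.table::setattr(tl, "encounter_id", eid)
  data.table::setattr(tl, "class", c("resolved_timeline", class(tl)))
  tl[]
}

#' Query a timeline over a trailing lookback window
#'
#' Returns the values of one concept observed in the half-open interval
#' `(at - lookback_h, at]`: the reading at the evaluation instant counts, a
#' reading exactly `lookback_h` hours old does not.
#'
#' @param timeline A [resolve_timeline()] result.
#' @param concept A single concept code.
#' @param at Evaluation timestamp.
#' @param lookback_h Window length in hours, > 0.
#' @return `data.table` with columns `event_time`, `value`, ascending in time;
#'   zero rows when nothing falls in the window.
#' @export
window_values <- function(timeline, concept, at, lookback_h) {
  stopifnot(length(lookback_h) == 1L, lookback_h > 0)
  .assert_concept(concept)
  at <- parse_clinical_time(at)
  cc <- concept
  concept_col <- event_time <- value <- NULL
  out <- timeline[timeline$concept == cc &
                    timeline$event_time > at - in_hours(lookback_h) &
                    timeline$event_time <= at,
                  c("event_time", "value")]
  data.table::setorder(out, event_time)
  out[]
}

#' @export
print.resolved_timeline <- function(x, ...) {
  cat("<resolved_timeline> encounter", attr(x, "encounter_id"),
      "-", nrow(x), "observations\n")
  NextMethod()
}
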