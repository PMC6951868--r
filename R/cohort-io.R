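# Cohort container and delimited-text / columnar IO for the four tables:
# encounters, observations, cultures, med_admins.

.DISPOSITIONS <- c("home_or_other", "expired", "hospice")

#' Assemble and validate an in-memory cohort
#'
#' Validates the four tables row-wise and assembles them into a
#' `sepsis_cohort`. Invalid rows are rejected (never silently repaired) and
#' counted per reason in the attached ingest report. Enforced rules:
#' encounters must have parseable admission/discharge with
#' `discharge_time > admit_time`, `age_years >= 18` (adult study population),
#' a known `sex` and `disposition`; observations must use a registered
#' concept, carry a finite value within its plausibility bounds, a parseable
#' timestamp and a non-negative `update_seq`, and must not duplicate the key
#' (`encounter_id`, `concept`, `event_time`, `update_seq`) nor tie the
#' correction counter for one clinical event; event rows referencing an
#' unknown encounter are rejected as orphans.
#'
#' @param encounters,observations,cultures,med_admins Data frames with the
#'   documented columns (see [write_cohort()] for the schemas).
#' @param quiet Suppress the ingest summary message.
#' @return A `sepsis_cohort`: a list of the four validated `data.table`s with
#'   attribute `ingest_report` (per-table rows read / kept / rejection
#'   reasons).
#' @export
as_cohort <- function(encounters, observations, cultures, med_admins,
                      quiet = FALSE) {
  report <- list()

  enc <- data.table::as.data.table(encounters)
  .require_cols(enc, c("encounter_id", "age_years", "sex", "admit_time",
                       "discharge_time", "disposition", "icu_within_48h"),
                "encounters")
  enc[, `:=`(encounter_id = as.character(encounter_id),
             age_years = suppressWarnings(as.integer(age_years)),
             sex = tolower(as.character(sex)),
             admit_time = parse_clinical_time(admit_time),
             discharge_time = parse_clinical_time(discharge_time),
             disposition = tolower(as.character(disposition)),
             icu_within_48h = as.logical(icu_within_48h))]
  reasons <- data.table::fcase(
    is.na(enc$admit_time) | is.na(enc$discharge_time), "unparseable_timestamp",
    enc$discharge_time <= enc$admit_time, "discharge_not_after_admit",
    is.na(enc$age_years) | enc$age_years < 18L, "age_below_18_or_missing",
    !enc$sex %in% c("female", "male"), "unknown_sex",
    !enc$disposition %in% .DISPOSITIONS, "unknown_disposition",
    default = NA_character_
  )
  report$encounters <- .tabulate_reasons(reasons, nrow(enc))
  enc <- enc[is.na(reasons)]
  known_ids <- enc$encounter_id

  obs <- data.table::as.data.table(observations)
  .require_cols(obs, c("encounter_id", "concept", "value", "event_time",
                       "update_seq"), "observations")
  obs[, `:=`(encounter_id = as.character(encounter_id),
             concept = as.character(concept),
             value = suppressWarnings(as.numeric(value)),
             event_time = parse_clinical_time(event_time),
             update_seq = suppressWarnings(as.integer(update_seq)))]
  obs <- merge(obs, .CONCEPTS, by = "concept", all.x = TRUE, sort = FALSE)
  reasons <- data.table::fcase(
    !obs$concept %in% .known_concepts(), "unknown_concept",
    is.na(obs$event_time), "unparseable_timestamp",
    !is.finite(obs$value), "missing_or_nonfinite_value",
    obs$value < obs$lower | obs$value > obs$upper, "value_outside_bounds",
    is.na(obs$update_seq) | obs$update_seq < 0L, "bad_update_seq",
    !obs$encounter_id %in% known_ids, "unknown_encounter",
    default = NA_character_
  )
  obs[, c("lower", "upper", "is_lab") := NULL]
  ok <- is.na(reasons)
  # exact duplicate key, and tied update counters for one clinical event,
  # are both data errors: every row of an offending group is rejected
  key <- c("encounter_id", "concept", "event_time", "update_seq")
  dup <- ok & (duplicated(obs, by = key) |
                 duplicated(obs, by = key, fromLast = TRUE))
  reasons[dup] <- "update_seq_tie"
  report$observations <- .tabulate_reasons(reasons, nrow(obs))
  obs <- obs[is.na(reasons)]
  data.table::setorder(obs, encounter_id, concept, event_time, update_seq)

  cul <- data.table::as.data.table(cultures)
  .require_cols(cul, c("encounter_id", "specimen", "collect_time"), "cultures")
  cul[, `:=`(encounter_id = as.character(encounter_id),
             specimen = as.character(specimen),
             collect_time = parse_clinical_time(collect_time))]
  reasons <- data.table::fcase(
    is.na(cul$collect_time), "unparseable_timestamp",
    !cul$encounter_id %in% known_ids, "unknown_encounter",
    default = NA_character_
  )
  report$cultures <- .tabulate_reasons(reasons, nrow(cul))
  cul <- cul[is.na(reasons)]

  med <- data.table::as.data.table(med_admins)
  .require_cols(med, c("encounter_id", "drug", "route", "admin_time"),
                "med_admins")
  med[, `:=`(encounter_id = as.character(encounter_id),
             drug = as.character(drug),
             route = as.character(route),
             admin_time = parse_clinical_time(admin_time))]
  reasons <- data.table::fcase(
    is.na(med$admin_time), "unparseable_timestamp",
    !med$encounter_id %in% known_ids, "unknown_encounter",
    default = NA_character_
  )
  report$med_admins <- .tabulate_reasons(reasons, nrow(med))
  med <- med[is.na(reasons)]

  cohort <- structure(
    list(encounters = enc[], observations = obs[], cultures = cul[],
         med_admins = med[]),
    ingest_report = report,
    class = "sepsis_cohort"
  )
  if (!quiet) {
    rej <- sum(vapply(report, function(r) r$rows_rejected, numeric(1)))
    message(sprintf("cohort: %d encounters, %d observations (%d rows rejected)",
                    nrow(enc), nrow(obs), rej))
  }
  cohort
}

.require_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("table '%s' is missing required column(s): %s",
                 table, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

.tabulate_reasons <- function(reasons, n) {
  tab <- table(reasons[!is.na(reasons)])
  list(rows_read = n,
       rows_kept = sum(is.na(reasons)),
       rows_rejected = n - sum(is.na(reasons)),
       reasons = as.list(tab))
}

#' Read a cohort from disk
#'
#' Reads the four tables (`encounters`, `observations`, `cultures`,
#' `med_admins`) from a directory, either as CSV (default) or as the
#' columnar-binary mirror (`dialect = "parquet"`, requires the arrow
#' package), then validates them via [as_cohort()].
#'
#' @param path Directory containing the tables.
#' @param dialect `"csv"` or `"parquet"`.
#' @param quiet Suppress the ingest summary message.
#' @return A `sepsis_cohort`; the ingest report is in
#'   `attr(cohort, "ingest_report")`.
#' @export
read_cohort <- function(path, dialect = c("csv", "parquet"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  tabs <- lapply(c("encounters", "observations", "cultures", "med_admins"),
                 function(tb) {
    if (dialect == "csv") {
      f <- file.path(path, paste0(tb, ".csv"))
      if (!file.exists(f)) stop("missing table file: ", f, call. = FALSE)
      data.table::fread(f, colClasses = list(character = "encounter_id"))
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the 'arrow' package is required for dialect = 'parquet'",
             call. = FALSE)
      }
      f <- file.path(path, paste0(tb, ".parquet"))
      if (!file.exists(f)) stop("missing table file: ", f, call. = FALSE)
      data.table::as.data.table(arrow::read_parquet(f))
    }
  })
  as_cohort(tabs[[1]], tabs[[2]], tabs[[3]], tabs[[4]], quiet = quiet)
}

#' Write a cohort to disk
#'
#' Emits the four tables with the documented headers. Schemas:
#' `encounters.csv` (encounter_id, age_years, sex, admit_time,
#' discharge_time, disposition, icu_within_48h), `observations.csv`
#' (encounter_id, concept, value, event_time, update_seq), `cultures.csv`
#' (encounter_id, specimen, collect_time), `med_admins.csv`
#' (encounter_id, drug, route, admin_time). Timestamps are written as
#' `YYYY-mm-dd HH:MM`.
#'
#' @param cohort A `sepsis_cohort`.
#' @param path Output directory (created if needed).
#' @param dialect `"csv"` or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = c("csv", "parquet")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cohort, "sepsis_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tb in names(cohort)) {
    out <- data.table::copy(cohort[[tb]])
    for (col in names(out)) {
      if (inherits(out[[col]], "POSIXct")) {
        data.table::set(out, j = col, value = format_clinical_time(out[[col]]))
      }
    }
    if (dialect == "csv") {
      data.table::fwrite(out, file.path(path, paste0(tb, ".csv")))
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the 'arrow' package is required for dialect = 'parquet'",
             call. = FALSE)
      }
      arrow::write_parquet(out, file.path(path, paste0(tb, ".parquet")))
    }
  }
  invisible(path)
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat("<sepsis_cohort>\n")
  cat("  encounters:  ", nrow(x$encounters), "\n")
  cat("  observations:", nrow(x$observations), "\n")
  cat("  cultures:    ", nrow(x$cultures), "\n")
  cat("  med_admins:  ", nrow(x$med_admins), "\n")
  invisible(x)
}
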