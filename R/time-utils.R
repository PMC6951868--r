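# Timestamps are timezone-naive (stored as UTC POSIXct) at minute resolution.

.TIME_FMT <- "%Y-%m-%d %H:%M"

#' Parse clinical timestamps
#'
#' Accepts ISO-8601-style timestamps with either a space or a `T` separator,
#' with or without seconds. Parsed times are truncated to minute resolution
#' and carry no timezone semantics (stored as UTC). Unparseable entries
#' become `NA` so that ingest can count and reject them.
#'
#' @param x Character vector of timestamps.
#' @return `POSIXct` vector, `NA` where unparseable.
#' @export
parse_clinical_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(floor_minute(x))
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = "%Y-%m-%d %H:%M")
  }
  floor_minute(out)
}

floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

format_clinical_time <- function(t) format(t, .TIME_FMT, tz = "UTC")

#' @rdname parse_clinical_time
#' @param h Numeric, hours.
#' @return `in_hours()`: the number of seconds in `h` hours.
#' @export
in_hours <- function(h) h * 3600
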