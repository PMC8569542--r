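# Time handling: all timestamps are ISO-8601, timezone-naive, read on a
# single clock (UTC internally). Dates sit at midnight. Durations are
# ISO-8601 literals; calendar units use fixed factors (see below) because
# screening arithmetic needs a total order, not civil calendars.

.SECONDS_PER_DAY <- 86400
.SECONDS_PER_YEAR <- 365.25 * 86400
.SECONDS_PER_MONTH <- .SECONDS_PER_YEAR / 12

#' Parse an ISO-8601 timestamp or date to epoch seconds
#'
#' Accepts `YYYY-MM-DD` or `YYYY-MM-DDTHH:MM:SS`; dates are taken at
#' midnight. All values are interpreted on a single timezone-naive clock.
#'
#' @param x character vector of timestamps.
#' @return numeric vector of seconds since 1970-01-01.
#' @export
parse_timestamp <- function(x) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s)) { out[[i]] <- NA_real_; next }
    fmt <- if (grepl("T", s, fixed = TRUE)) "%Y-%m-%dT%H:%M:%S" else "%Y-%m-%d"
    t <- as.POSIXct(s, format = fmt, tz = "UTC")
    if (is.na(t)) stop("cannot parse timestamp: ", s, call. = FALSE)
    out[[i]] <- as.numeric(t)
  }
  out
}

#' Format epoch seconds as an ISO-8601 timestamp
#' @param x numeric vector of epoch seconds.
#' @return character vector `YYYY-MM-DDTHH:MM:SS`.
#' @export
format_timestamp <- function(x) {
  format(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%S")
}

# Duration literal regex: at least one component required.
.DUR_RE <- "^P(?:([0-9]+)Y)?(?:([0-9]+)M)?(?:([0-9]+)W)?(?:([0-9]+)D)?(?:T(?:([0-9]+)H)?(?:([0-9]+)M)?(?:([0-9]+(?:\\.[0-9]+)?)S)?)?$"

#' Parse an ISO-8601 duration literal to seconds
#'
#' Supports `PnYnMnWnDTnHnMnS`. Months count 30.4375 days and years
#' 365.25 days, so durations form a fixed linear scale.
#'
#' @param x a single duration string such as `"PT48H"` or `"P20Y"`.
#' @return duration in seconds (numeric scalar).
#' @export
parse_duration <- function(x) {
  m <- regmatches(x, regexec(.DUR_RE, x, perl = TRUE))[[1]]
  if (length(m) == 0 || x == "P" || x == "PT")
    stop("cannot parse duration literal: ", x, call. = FALSE)
  num <- function(s) if (s == "") 0 else as.numeric(s)
  if (all(m[-1] == "")) stop("empty duration literal: ", x, call. = FALSE)
  num(m[2]) * .SECONDS_PER_YEAR + num(m[3]) * .SECONDS_PER_MONTH +
    num(m[4]) * 7 * .SECONDS_PER_DAY + num(m[5]) * .SECONDS_PER_DAY +
    num(m[6]) * 3600 + num(m[7]) * 60 + num(m[8])
}

#' Format seconds as a canonical ISO-8601 duration literal
#'
#' Canonical form uses days/hours/minutes/seconds only (calendar units are
#' not recovered), except that exact multiples of the year factor are
#' written as `PnY` so age-style literals round-trip.
#'
#' @param s duration in seconds (non-negative).
#' @return duration literal string.
#' @export
format_duration <- function(s) {
  if (s < 0) stop("negative duration", call. = FALSE)
  if (s == 0) return("PT0S")
  if (s %% .SECONDS_PER_YEAR == 0) return(paste0("P", s / .SECONDS_PER_YEAR, "Y"))
  out <- "P"
  d <- s %/% .SECONDS_PER_DAY; s <- s %% .SECONDS_PER_DAY
  if (d > 0) out <- paste0(out, d, "D")
  if (s > 0) {
    out <- paste0(out, "T")
    h <- s %/% 3600; s <- s %% 3600
    mi <- s %/% 60; s <- s %% 60
    if (h > 0) out <- paste0(out, h, "H")
    if (mi > 0) out <- paste0(out, mi, "M")
    if (s > 0) out <- paste0(out, s, "S")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
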