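#' Meal time slots
#'
#' Operating windows of the three campus meal services, in seconds since
#' midnight. Breakfast runs 06:30--08:30, lunch 11:00--13:00 and dinner
#' 17:30--19:30; both bounds are inclusive. The windows come from the
#' cafeterias' hours of operation and drive both meal-slot classification
#' and the synthetic generator's truncation of drawn meal times.
#'
#' @return A data.frame with columns `meal_class`, `slot_start`, `slot_end`
#'   (seconds since midnight), one row per meal class in canonical order
#'   breakfast, lunch, dinner.
#' @export
#' @examples
#' meal_slots()
meal_slots <- function() {
  data.frame(
    meal_class = c("breakfast", "lunch", "dinner"),
    slot_start = c(6.5, 11, 17.5) * 3600,
    slot_end   = c(8.5, 13, 19.5) * 3600,
    stringsAsFactors = FALSE
  )
}

MEAL_CLASSES <- c("breakfast", "lunch", "dinner")

# the 7 non-empty subsets of {breakfast, lunch, dinner}
ALLDAY_PATTERNS <- c("B", "L", "D", "BL", "LD", "BD", "BLD")

#' Convert "HH:MM:SS" to seconds since midnight
#'
#' @param x character vector of clock times.
#' @return integer vector of seconds since midnight.
#' @export
hms_to_seconds <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || anyNA(p)) stop("malformed clock time; expected HH:MM:SS")
    as.integer(p[1] * 3600 + p[2] * 60 + p[3])
  }, integer(1))
}

#' Convert seconds since midnight to "HH:MM:SS"
#'
#' @param s numeric vector, seconds since midnight in [0, 86400).
#' @return character vector of clock times.
#' @export
seconds_to_hms <- function(s) {
  s <- as.integer(round(s))
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

#' Label dates as weekday or weekend
#'
#' Day type is taken from the civil day of week; an optional override list
#' forces specific dates (e.g. national holidays falling on weekdays) to
#' count as weekend days. The default is the pure day-of-week rule.
#'
#' @param dates a `Date` vector.
#' @param holiday_dates optional `Date` vector treated as weekend.
#' @return character vector, `"weekday"` or `"weekend"`.
#' @export
day_type_of <- function(dates, holiday_dates = NULL) {
  dates <- as.Date(dates)
  wd <- as.POSIXlt(dates)$wday   # 0 = Sunday, 6 = Saturday
  out <- ifelse(wd == 0L | wd == 6L, "weekend", "weekday")
  if (!is.null(holiday_dates)) out[dates %in% as.Date(holiday_dates)] <- "weekend"
  out
}

#' Build the study calendar
#'
#' The observation month is October 1--31, 2020, labelled weekday/weekend
#' by day of week (with an optional holiday override).
#'
#' @param from,to first and last date (defaults: the October 2020 window).
#' @param holiday_dates optional dates forced to weekend.
#' @return data.frame with columns `date` (Date) and `day_type`.
#' @export
#' @examples
#' cal <- study_calendar()
#' table(cal$day_type)  # 22 weekdays, 9 weekend days
study_calendar <- function(from = as.Date("2020-10-01"),
                           to = as.Date("2020-10-31"),
                           holiday_dates = NULL) {
  from <- as.Date(from); to <- as.Date(to)
  if (to < from) stop("calendar end precedes start")
  dates <- seq(from, to, by = "day")
  data.frame(date = dates, day_type = day_type_of(dates, holiday_dates),
             stringsAsFactors = FALSE)
}

# Derive a per-stage seed from a global seed so stages are independently
# reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399) + 1L
}
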