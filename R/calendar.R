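# Calendar machinery shared by the climatology and detection code.
#
# Three model calendars are supported: "standard" (proleptic Gregorian with
# leap days), "noleap" (365-day) and "360_day" (12 months of 30 days).
# Thresholds are indexed by (month, day) keys; on the standard calendar
# Feb 29 is its own key and simply contributes nothing in non-leap years.

.CALENDARS <- c("standard", "noleap", "360_day")

.isLeap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

.monthLengths <- function(calendar, year = NULL) {
  if (calendar == "360_day") return(rep(30L, 12L))
  m <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  if (calendar == "standard" && !is.null(year) && .isLeap(year)) m[2L] <- 29L
  m
}

#' Calendar-day keys of a model calendar
#'
#' All (month, day) pairs a calendar can realise, in calendar order. The
#' standard calendar has 366 keys (Feb 29 included), "noleap" 365 and
#' "360_day" 360.
#'
#' @param calendar one of `"standard"`, `"noleap"`, `"360_day"`.
#' @return data.frame with integer columns `month` and `day`.
#' @export
calendarKeys <- function(calendar = "standard") {
  calendar <- match.arg(calendar, .CALENDARS)
  ml <- .monthLengths(calendar)
  if (calendar == "standard") ml[2L] <- 29L
  data.frame(
    month = rep.int(seq_len(12L), ml),
    day   = unlist(lapply(ml, seq_len), use.names = FALSE)
  )
}

.nKeys <- function(calendar) {
  switch(calendar, standard = 366L, noleap = 365L, `360_day` = 360L)
}

# 12 x 31 lookup: (month, day) -> key position (NA where the day cannot exist)
.keyLookup <- function(calendar) {
  keys <- calendarKeys(calendar)
  lk <- matrix(NA_integer_, 12L, 31L)
  lk[cbind(keys$month, keys$day)] <- seq_len(nrow(keys))
  lk
}

.keyIndex <- function(month, day, calendar) {
  .keyLookup(calendar)[cbind(month, day)]
}

# Absolute day number used for contiguity checks; consecutive calendar days
# differ by exactly 1.
.dayNumber <- function(year, month, day, calendar) {
  if (calendar == "360_day") {
    return(year * 360 + (month - 1L) * 30 + (day - 1L))
  }
  if (calendar == "noleap") {
    cum <- cumsum(c(0L, .monthLengths("noleap")[-12L]))
    return(year * 365 + cum[month] + (day - 1L))
  }
  as.numeric(as.Date(sprintf("%04d-%02d-%02d", year, month, day)))
}

# Does (month, day) exist in `year` on this calendar?
.dayExists <- function(month, day, year, calendar) {
  if (calendar == "standard") {
    !(month == 2L & day == 29L & !.isLeap(year))
  } else {
    rep(TRUE, length(year) * (length(month) > 0))
  }
}

# Full calendar of one year as a data.frame(year, month, day).
.yearCalendar <- function(year, calendar) {
  ml <- .monthLengths(calendar, year)
  data.frame(
    year  = year,
    month = rep.int(seq_len(12L), ml),
    day   = unlist(lapply(ml, seq_len), use.names = FALSE)
  )
}

.yearLength <- function(year, calendar) {
  switch(calendar,
    standard = ifelse(.isLeap(year), 366L, 365L),
    noleap = 365L,
    `360_day` = 360L
  )
}

# Circular window of key positions: the +/- half positions around each key.
# Returns an nKeys x windowDays integer matrix (1-based).
.windowPositions <- function(calendar, windowDays) {
  K <- .nKeys(calendar)
  half <- (windowDays - 1L) %/% 2L
  offs <- seq.int(-half, half)
  outer(seq_len(K) - 1L, offs, function(k, o) ((k + o) %% K) + 1L)
}
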