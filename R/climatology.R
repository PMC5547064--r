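# Reference-period climatology: windowed calendar-day percentile thresholds
# and the annual-maximum normalisation pair.
#
# Quantile convention: the empirical-distribution linear-interpolation
# estimator (R's type 7), used identically for the daily thresholds, the
# t25/t75 pair and every bootstrap surrogate.

# Reshape a series into (calendar-day key) x (reference year) matrices plus
# bookkeeping shared by the plain and bootstrap threshold paths.
.climPrep <- function(series, refYears, windowDays) {
  calendar <- series@calendar
  K <- .nKeys(calendar)
  N <- length(refYears)
  keyIdx <- .keyIndex(series@month, series@day, calendar)
  values <- matrix(NA_real_, K, N)
  inRef <- series@year %in% refYears
  col <- match(series@year[inRef], refYears)
  values[cbind(keyIdx[inRef], col)] <- series@tmax[inRef]
  keys <- calendarKeys(calendar)
  exists <- matrix(TRUE, K, N)
  if (calendar == "standard") {
    feb29 <- which(keys$month == 2L & keys$day == 29L)
    exists[feb29, !.isLeap(refYears)] <- FALSE
  }
  annualMax <- suppressWarnings(apply(values, 2L, max, na.rm = TRUE))
  annualMax[!is.finite(annualMax)] <- NA_real_
  list(values = values, exists = exists,
       windows = .windowPositions(calendar, windowDays) - 1L,
       annualMax = annualMax, refYears = refYears,
       calendar = calendar, keyIdx = keyIdx)
}

.checkReference <- function(series, referencePeriod) {
  refYears <- seq.int(referencePeriod[1], referencePeriod[2])
  if (!all(refYears %in% series@year)) {
    stop(sprintf("reference period %d-%d is not fully covered by the series (%d-%d)",
                 referencePeriod[1], referencePeriod[2],
                 min(series@year), max(series@year)))
  }
  refYears
}

#' Calendar-day percentile thresholds
#'
#' For every calendar day, pools all reference-period values whose calendar
#' day lies within the centred window (default ±15 days, wrapping across the
#' year boundary) and returns the pooled sample quantile (default the 90th
#' percentile). A day's threshold is `NA` (with a warning) when fewer than
#' `minFrac` of its nominal pool is non-missing.
#'
#' @param series a [DailyClimateSeries-class].
#' @param referencePeriod integer `c(first, last)` reference years
#'   (default 1981–2010).
#' @param windowDays odd window width in days (default 31).
#' @param quantileProb threshold quantile (default 0.90).
#' @param minFrac completeness guard: minimum non-missing fraction of the
#'   nominal pool (default 0.8).
#' @return numeric vector of thresholds, one per calendar-day key (see
#'   [calendarKeys()]).
#' @export
dailyThreshold <- function(series, referencePeriod = c(1981L, 2010L),
                           windowDays = 31L, quantileProb = 0.9,
                           minFrac = 0.8) {
  if (windowDays %% 2L == 0L) stop("windowDays must be odd")
  refYears <- .checkReference(series, referencePeriod)
  prep <- .climPrep(series, refYears, windowDays)
  thr <- .cppWindowQuantiles(prep$values, prep$exists, prep$windows,
                             seq_along(refYears) - 1L, quantileProb, minFrac)
  if (anyNA(thr)) {
    warning(sprintf("%d calendar day(s) have insufficient reference data; thresholds set to NA",
                    sum(is.na(thr))))
  }
  keys <- calendarKeys(prep$calendar)
  names(thr) <- sprintf("%02d-%02d", keys$month, keys$day)
  thr
}

#' Percentiles of reference-period annual maxima
#'
#' Computes the annual maximum of daily `tmax` for each reference year, then
#' the 25th and 75th percentiles of those annual maxima — the normalisation
#' pair of the daily heat-wave magnitude.
#'
#' @inheritParams dailyThreshold
#' @param variable `"tmax"` (default) or `"apparent"`: with `"apparent"` the
#'   annual maxima are taken over `max(tmax, AT)` per day, which requires
#'   humidity.
#' @return named numeric `c(t25, t75)` in °C.
#' @export
annualMaxPercentiles <- function(series, referencePeriod = c(1981L, 2010L),
                                 variable = c("tmax", "apparent")) {
  variable <- match.arg(variable)
  refYears <- .checkReference(series, referencePeriod)
  vals <- series@tmax
  if (variable == "apparent") {
    if (!hasRhmin(series)) stop("apparent normalisation requires rhmin")
    at <- apparentTemperatureC(series@tmax, series@rhmin)
    vals <- pmax(vals, at, na.rm = TRUE)
    vals[is.na(series@tmax)] <- NA_real_
  }
  amax <- vapply(refYears, function(y) {
    v <- vals[series@year == y]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(amax)) {
    warning(sprintf("%d reference year(s) fully missing; excluded from annual maxima",
                    sum(is.na(amax))))
    amax <- amax[!is.na(amax)]
  }
  if (length(amax) < 2L) stop("fewer than 2 usable reference years for annual maxima")
  q <- quantile(amax, c(0.25, 0.75), type = 7, names = FALSE)
  c(t25 = q[1], t75 = q[2])
}

#' Build a threshold climatology
#'
#' Convenience wrapper combining [dailyThreshold()] and
#' [annualMaxPercentiles()] into a [ThresholdClimatology-class] object. Pass
#' `apparentNormalization = TRUE` to additionally store an
#' apparent-temperature based normalisation pair (`at25`/`at75`) for the
#' alternative AHWI normalisation mode.
#'
#' @inheritParams dailyThreshold
#' @param apparentNormalization also compute the AT-based pair (needs rhmin).
#' @return a [ThresholdClimatology-class].
#' @examples
#' cfg <- synthConfig(years = 1981:2012, seed = 1)
#' s <- generateSeries(cfg)
#' thresholdClimatology(s, c(1981L, 2010L))
#' @export
thresholdClimatology <- function(series, referencePeriod = c(1981L, 2010L),
                                 windowDays = 31L, quantileProb = 0.9,
                                 minFrac = 0.8, apparentNormalization = FALSE) {
  thr <- dailyThreshold(series, referencePeriod, windowDays, quantileProb, minFrac)
  tq <- annualMaxPercentiles(series, referencePeriod)
  atq <- c(NA_real_, NA_real_)
  if (apparentNormalization) {
    atq <- annualMaxPercentiles(series, referencePeriod, variable = "apparent")
  }
  new("ThresholdClimatology",
      dailyQ90 = thr, t25 = unname(tq[1]), t75 = unname(tq[2]),
      at25 = unname(atq[1]), at75 = unname(atq[2]),
      referencePeriod = as.integer(referencePeriod),
      windowDays = as.integer(windowDays), quantileProb = quantileProb,
      calendar = series@calendar)
}

# Internal fast constructor used by the bootstrap loop (skips recomputation
# of names and the prep step).
.climFromParts <- function(thr, tq, referencePeriod, windowDays, quantileProb, calendar) {
  new("ThresholdClimatology",
      dailyQ90 = thr, t25 = tq[1], t75 = tq[2],
      at25 = NA_real_, at75 = NA_real_,
      referencePeriod = as.integer(referencePeriod),
      windowDays = as.integer(windowDays), quantileProb = quantileProb,
      calendar = calendar)
}
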