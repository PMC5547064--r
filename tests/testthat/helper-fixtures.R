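# Shared fixtures, built in code.

# A one-year standard-calendar series with a prescribed tmax vector placed
# from a given start date; remaining days filled with a cool constant.
toyYearSeries <- function(values, startMonth, startDay, year = 2001,
                          fill = 10, rhmin = NULL) {
  cal <- humidheat:::.yearCalendar(year, "standard")
  tmax <- rep(fill, nrow(cal))
  i0 <- which(cal$month == startMonth & cal$day == startDay)
  tmax[seq.int(i0, i0 + length(values) - 1L)] <- values
  rh <- NULL
  if (!is.null(rhmin)) {
    rh <- rep(50, nrow(cal))
    rh[seq.int(i0, i0 + length(values) - 1L)] <- rhmin
  }
  dailyClimateSeries(tmax = tmax, rhmin = rh, year = cal$year,
                     month = cal$month, day = cal$day)
}

# A climatology with a flat daily threshold and a given normalisation pair.
flatClimatology <- function(threshold, t25, t75, calendar = "standard",
                            referencePeriod = c(1981L, 2010L)) {
  new("ThresholdClimatology",
      dailyQ90 = rep(threshold, humidheat:::.nKeys(calendar)),
      t25 = t25, t75 = t75, at25 = NA_real_, at75 = NA_real_,
      referencePeriod = as.integer(referencePeriod),
      windowDays = 31L, quantileProb = 0.9, calendar = calendar)
}

# Independent scalar implementation of the NOAA fact-sheet heat index,
# written as a plain branch-by-branch transcription (the oracle for the
# vectorised implementation).
oracleHeatIndex <- function(t, r) {
  simple <- 0.5 * (t + 61.0 + (t - 68.0) * 1.2 + r * 0.094)
  if ((simple + t) / 2 < 80) return(simple)
  hi <- -42.379 + 2.04901523 * t + 10.14333127 * r - 0.22475541 * t * r -
    6.83783e-3 * t^2 - 5.481717e-2 * r^2 + 1.22874e-3 * t^2 * r +
    8.5282e-4 * t * r^2 - 1.99e-6 * t^2 * r^2
  if (r < 13 && t >= 80 && t <= 112) {
    hi <- hi - ((13 - r) / 4) * sqrt((17 - abs(t - 95)) / 17)
  }
  if (r > 85 && t >= 80 && t <= 87) {
    hi <- hi + ((r - 85) / 10) * ((87 - t) / 2)
  }
  hi
}
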