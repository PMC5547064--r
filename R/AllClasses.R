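#' DailyClimateSeries: one location's daily Tmax and RHmin
#'
#' Holds a contiguous daily series of maximum temperature (°C) and,
#' optionally, minimum relative humidity (%) on an explicit model calendar.
#' Gaps are represented as `NA` values on an unbroken date axis, never as
#' skipped dates.
#'
#' @slot year,month,day integer vectors, one entry per day, contiguous on the
#'   series calendar.
#' @slot tmax numeric, daily maximum temperature in °C (`NA` allowed).
#' @slot rhmin numeric, daily minimum relative humidity in % within
#'   \[0, 100\] (`NA` allowed); `numeric(0)` when humidity is unavailable.
#' @slot calendar `"standard"`, `"noleap"` or `"360_day"`.
#' @slot locationId character label.
#' @slot lat,lon numeric coordinates in degrees (`NA` when unknown).
#' @export
setClass("DailyClimateSeries",
  representation(
    year = "integer", month = "integer", day = "integer",
    tmax = "numeric", rhmin = "numeric",
    calendar = "character", locationId = "character",
    lat = "numeric", lon = "numeric"
  ),
  prototype(calendar = "standard", locationId = "site", lat = NA_real_, lon = NA_real_)
)

setValidity("DailyClimateSeries", function(object) {
  n <- length(object@year)
  msg <- character()
  if (!(object@calendar %in% .CALENDARS)) {
    msg <- c(msg, sprintf("unknown calendar '%s'", object@calendar))
  }
  if (length(object@month) != n || length(object@day) != n || length(object@tmax) != n) {
    msg <- c(msg, "year, month, day and tmax must have equal length")
  }
  if (!(length(object@rhmin) %in% c(0L, n))) {
    msg <- c(msg, "rhmin must be empty or match the series length")
  }
  if (length(object@rhmin) && any(object@rhmin < 0 | object@rhmin > 100, na.rm = TRUE)) {
    msg <- c(msg, "rhmin values must lie in [0, 100] or be NA")
  }
  if (!length(msg) && n > 1L) {
    dn <- .dayNumber(object@year, object@month, object@day, object@calendar)
    if (any(diff(dn) != 1)) {
      msg <- c(msg, "dates must be strictly increasing with a daily step (use NA for gaps)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClimateGrid: a rectilinear collection of daily series
#'
#' A lat x lon grid of [DailyClimateSeries] objects sharing one calendar.
#' Cells are stored column-major in latitude (index `(iLon - 1) * nLat + iLat`).
#'
#' @slot lats,lons ascending numeric coordinate vectors (degrees).
#' @slot series list of `DailyClimateSeries`, length `nLat * nLon`.
#' @export
setClass("ClimateGrid",
  representation(lats = "numeric", lons = "numeric", series = "list")
)

setValidity("ClimateGrid", function(object) {
  msg <- character()
  if (length(object@series) != length(object@lats) * length(object@lons)) {
    msg <- c(msg, "series list must have length nLat * nLon")
  }
  if (is.unsorted(object@lats, strictly = TRUE)) msg <- c(msg, "lats must be strictly ascending")
  if (is.unsorted(object@lons, strictly = TRUE)) msg <- c(msg, "lons must be strictly ascending")
  if (!all(vapply(object@series, is, logical(1), "DailyClimateSeries"))) {
    msg <- c(msg, "all grid cells must be DailyClimateSeries objects")
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdClimatology: calendar-day thresholds and normalisation percentiles
#'
#' Per-calendar-day exceedance thresholds (the windowed 90th percentile of the
#' reference period by default) together with the 25th/75th percentiles of the
#' reference-period annual maxima that normalise daily heat-wave magnitudes.
#'
#' @slot dailyQ90 numeric, one threshold (°C) per calendar-day key of the
#'   calendar (366/365/360 values); `NA` where the reference pool was too
#'   incomplete.
#' @slot t25,t75 numeric(1), percentiles (°C) of the reference annual maxima.
#' @slot at25,at75 numeric(1), optional apparent-temperature based
#'   normalisation pair (NA unless requested).
#' @slot referencePeriod integer(2), first and last reference year.
#' @slot windowDays odd integer, pooling window width (days).
#' @slot quantileProb numeric(1), threshold quantile (default 0.90).
#' @slot calendar calendar name.
#' @export
setClass("ThresholdClimatology",
  representation(
    dailyQ90 = "numeric", t25 = "numeric", t75 = "numeric",
    at25 = "numeric", at75 = "numeric",
    referencePeriod = "integer", windowDays = "integer",
    quantileProb = "numeric", calendar = "character"
  ),
  prototype(at25 = NA_real_, at75 = NA_real_, windowDays = 31L,
            quantileProb = 0.9, calendar = "standard")
)

setValidity("ThresholdClimatology", function(object) {
  msg <- character()
  if (!(object@calendar %in% .CALENDARS)) {
    msg <- c(msg, sprintf("unknown calendar '%s'", object@calendar))
  } else if (length(object@dailyQ90) != .nKeys(object@calendar)) {
    msg <- c(msg, sprintf("dailyQ90 must have %d values on the %s calendar",
                          .nKeys(object@calendar), object@calendar))
  }
  if (length(object@referencePeriod) != 2L) {
    msg <- c(msg, "referencePeriod must be (first, last) year")
  }
  if (!is.na(object@t25) && !is.na(object@t75) && object@t25 > object@t75) {
    msg <- c(msg, "t25 must not exceed t75")
  }
  if (object@windowDays < 1L || object@windowDays %% 2L == 0L) {
    msg <- c(msg, "windowDays must be a positive odd integer")
  }
  if (object@quantileProb <= 0 || object@quantileProb >= 1) {
    msg <- c(msg, "quantileProb must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' WarmingLevelSample: model-years at a global warming level
#'
#' The pooled set of (run, year) pairs whose global-mean temperature anomaly
#' relative to the baseline period falls within the closed window
#' `[level - halfwidth, level + halfwidth]`.
#'
#' @slot level nominal warming level (°C above baseline).
#' @slot halfwidth window half-width (°C).
#' @slot members data.frame with columns `run`, `year`, `anomaly`.
#' @slot baselinePeriod integer(2) baseline years.
#' @export
setClass("WarmingLevelSample",
  representation(level = "numeric", halfwidth = "numeric",
                 members = "data.frame", baselinePeriod = "integer"),
  prototype(halfwidth = 0.1, baselinePeriod = c(1861L, 1880L))
)

setValidity("WarmingLevelSample", function(object) {
  msg <- character()
  if (!all(c("run", "year", "anomaly") %in% names(object@members))) {
    msg <- c(msg, "members must have columns run, year, anomaly")
  } else {
    a <- object@members$anomaly
    if (any(a < object@level - object@halfwidth - 1e-12 |
            a > object@level + object@halfwidth + 1e-12, na.rm = TRUE)) {
      msg <- c(msg, "all member anomalies must lie within the level window")
    }
  }
  if (object@halfwidth <= 0) msg <- c(msg, "halfwidth must be positive")
  if (length(msg)) msg else TRUE
})

#' SynthConfig: synthetic daily weather configuration
#'
#' Parameters of the seeded generator: a sinusoidal seasonal cycle plus AR(1)
#' temperature anomalies, relative humidity generated conditionally on the
#' temperature anomaly with a negative coupling slope, an optional secular
#' trend, and injectable multi-day heat-wave bumps.
#'
#' @slot years integer vector of simulated years (contiguous).
#' @slot lats,lons grid coordinates (length 1 for a single site).
#' @slot baseMeanC annual-mean Tmax at the reference latitude (°C).
#' @slot latGradient °C change of the annual mean per degree latitude.
#' @slot seasonalAmpC seasonal half-range of the Tmax cycle (°C).
#' @slot ar1 lag-1 autocorrelation of daily anomalies, in \[0, 1).
#' @slot dailySdC stationary standard deviation of daily anomalies (°C).
#' @slot tRhCoupling slope of RHmin on the temperature anomaly (%/°C,
#'   negative by default).
#' @slot rhMean,rhSd mean and independent-noise SD of RHmin (%).
#' @slot trendPerDecade linear warming trend (°C/decade).
#' @slot events data.frame of injected events with columns `year`,
#'   `startDay` (day of year), `duration`, `amplitude` (°C), `rhBoost` (%).
#' @slot seed integer RNG seed; identical seed + config gives bit-identical
#'   output.
#' @slot calendar calendar name.
#' @export
setClass("SynthConfig",
  representation(
    years = "integer", lats = "numeric", lons = "numeric",
    baseMeanC = "numeric", latGradient = "numeric", seasonalAmpC = "numeric",
    ar1 = "numeric", dailySdC = "numeric",
    tRhCoupling = "numeric", rhMean = "numeric", rhSd = "numeric",
    trendPerDecade = "numeric", events = "data.frame",
    seed = "integer", calendar = "character"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (!length(object@years) || any(diff(object@years) != 1L)) {
    msg <- c(msg, "years must be a contiguous integer sequence")
  }
  if (object@ar1 < 0 || object@ar1 >= 1) msg <- c(msg, "ar1 must lie in [0, 1)")
  if (object@dailySdC < 0) msg <- c(msg, "dailySdC must be non-negative")
  if (object@rhMean < 0 || object@rhMean > 100) msg <- c(msg, "rhMean must lie in [0, 100]")
  if (!(object@calendar %in% .CALENDARS)) msg <- c(msg, "unknown calendar")
  ev <- object@events
  need <- c("year", "startDay", "duration", "amplitude", "rhBoost")
  if (nrow(ev) && !all(need %in% names(ev))) {
    msg <- c(msg, paste("events needs columns", paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})
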