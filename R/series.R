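#' Construct a daily climate series
#'
#' @param tmax numeric vector of daily maximum temperatures (°C).
#' @param rhmin optional numeric vector of daily minimum relative humidity
#'   (%, in \[0, 100\]); `NULL` for temperature-only series.
#' @param dates `Date` vector (standard calendar only); alternative to
#'   `year`/`month`/`day`.
#' @param year,month,day integer date components (any supported calendar).
#' @param calendar `"standard"`, `"noleap"` or `"360_day"`.
#' @param locationId character label for the site.
#' @param lat,lon coordinates in degrees.
#' @return a [DailyClimateSeries-class] object.
#' @examples
#' d <- seq(as.Date("2000-06-01"), by = "day", length.out = 10)
#' dailyClimateSeries(tmax = 25 + 1:10, dates = d)
#' @export
dailyClimateSeries <- function(tmax, rhmin = NULL, dates = NULL,
                               year = NULL, month = NULL, day = NULL,
                               calendar = "standard", locationId = "site",
                               lat = NA_real_, lon = NA_real_) {
  calendar <- match.arg(calendar, .CALENDARS)
  if (!is.null(dates)) {
    if (calendar != "standard") {
      stop("Date input is only meaningful on the standard calendar; supply year/month/day")
    }
    dates <- as.Date(dates)
    lt <- as.POSIXlt(dates)
    year <- lt$year + 1900L
    month <- lt$mon + 1L
    day <- lt$mday
  }
  if (is.null(year) || is.null(month) || is.null(day)) {
    stop("supply either `dates` or all of `year`, `month`, `day`")
  }
  new("DailyClimateSeries",
      year = as.integer(year), month = as.integer(month), day = as.integer(day),
      tmax = as.numeric(tmax),
      rhmin = if (is.null(rhmin)) numeric(0) else as.numeric(rhmin),
      calendar = calendar, locationId = as.character(locationId),
      lat = as.numeric(lat), lon = as.numeric(lon))
}

#' @describeIn dailyClimateSeries number of days in the series
#' @param x,object a `DailyClimateSeries`.
#' @export
setMethod("length", "DailyClimateSeries", function(x) length(x@tmax))

#' Accessors for DailyClimateSeries
#'
#' `seriesTmax()`, `seriesRhmin()`, `seriesCalendar()`, `seriesYears()` and
#' `hasRhmin()` read the corresponding components; `seriesDates()` returns the
#' `Date` axis (standard calendar only).
#'
#' @param x a [DailyClimateSeries-class].
#' @return the requested component.
#' @export
seriesTmax <- function(x) x@tmax

#' @rdname seriesTmax
#' @export
seriesRhmin <- function(x) if (length(x@rhmin)) x@rhmin else rep(NA_real_, length(x@tmax))

#' @rdname seriesTmax
#' @export
hasRhmin <- function(x) length(x@rhmin) > 0L

#' @rdname seriesTmax
#' @export
seriesCalendar <- function(x) x@calendar

#' @rdname seriesTmax
#' @export
seriesYears <- function(x) sort(unique(x@year))

#' @rdname seriesTmax
#' @export
seriesDates <- function(x) {
  if (x@calendar != "standard") {
    stop("seriesDates() is defined for the standard calendar; use as.data.frame()")
  }
  as.Date(sprintf("%04d-%02d-%02d", x@year, x@month, x@day))
}

#' @export
#' @method as.data.frame DailyClimateSeries
as.data.frame.DailyClimateSeries <- function(x, ...) {
  df <- data.frame(year = x@year, month = x@month, day = x@day, tmax = x@tmax)
  if (hasRhmin(x)) df$rhmin <- x@rhmin
  df
}

setMethod("show", "DailyClimateSeries", function(object) {
  n <- length(object@tmax)
  cat(sprintf("DailyClimateSeries '%s' (%s calendar): %d days, %d-%d\n",
              object@locationId, object@calendar, n,
              if (n) min(object@year) else NA, if (n) max(object@year) else NA))
  cat(sprintf("  tmax: %d missing; rhmin: %s\n",
              sum(is.na(object@tmax)),
              if (hasRhmin(object)) sprintf("%d missing", sum(is.na(object@rhmin)))
              else "absent"))
})

# Restrict a series to a span of years (keeps contiguity).
.subsetYears <- function(series, years) {
  keep <- series@year %in% years
  new("DailyClimateSeries",
      year = series@year[keep], month = series@month[keep], day = series@day[keep],
      tmax = series@tmax[keep],
      rhmin = if (hasRhmin(series)) series@rhmin[keep] else numeric(0),
      calendar = series@calendar, locationId = series@locationId,
      lat = series@lat, lon = series@lon)
}

#' Construct a climate grid
#'
#' @param lats,lons strictly ascending coordinate vectors (degrees).
#' @param series list of [DailyClimateSeries-class] cells, latitude-major
#'   (cell `(iLat, iLon)` at index `(iLon - 1) * nLat + iLat`).
#' @return a [ClimateGrid-class].
#' @export
climateGrid <- function(lats, lons, series) {
  new("ClimateGrid", lats = as.numeric(lats), lons = as.numeric(lons),
      series = series)
}

#' @describeIn climateGrid extract the series of one cell
#' @param grid a `ClimateGrid`.
#' @param iLat,iLon 1-based cell indices.
#' @export
gridCell <- function(grid, iLat, iLon) {
  grid@series[[(iLon - 1L) * length(grid@lats) + iLat]]
}

#' @describeIn climateGrid grid coordinates as a data.frame (lat-major order)
#' @export
gridCoords <- function(grid) {
  data.frame(lat = rep(grid@lats, times = length(grid@lons)),
             lon = rep(grid@lons, each = length(grid@lats)))
}

setMethod("show", "ClimateGrid", function(object) {
  cat(sprintf("ClimateGrid: %d x %d cells (lat %g..%g, lon %g..%g)\n",
              length(object@lats), length(object@lons),
              min(object@lats), max(object@lats),
              min(object@lons), max(object@lons)))
})

setMethod("show", "ThresholdClimatology", function(object) {
  cat(sprintf("ThresholdClimatology (%s calendar, ref %d-%d)\n",
              object@calendar, object@referencePeriod[1], object@referencePeriod[2]))
  cat(sprintf("  q%.0f threshold: %d calendar days (%d missing), window %d days\n",
              100 * object@quantileProb, length(object@dailyQ90),
              sum(is.na(object@dailyQ90)), object@windowDays))
  cat(sprintf("  annual-max normalisation: t25 = %.2f, t75 = %.2f °C\n",
              object@t25, object@t75))
})

setMethod("show", "WarmingLevelSample", function(object) {
  cat(sprintf("WarmingLevelSample: %.2f °C ± %.2f relative to %d-%d, %d member-years\n",
              object@level, object@halfwidth,
              object@baselinePeriod[1], object@baselinePeriod[2],
              nrow(object@members)))
})

#' Accessors for ThresholdClimatology and WarmingLevelSample
#'
#' @param x the object.
#' @return `dailyQ90()` the per-calendar-day threshold vector;
#'   `refPercentiles()` the named `c(t25, t75)` pair; `sampleSize()` the
#'   number of member-years; `sampleMembers()` the member data.frame.
#' @export
dailyQ90 <- function(x) x@dailyQ90

#' @rdname dailyQ90
#' @export
refPercentiles <- function(x) c(t25 = x@t25, t75 = x@t75)

#' @rdname dailyQ90
#' @export
sampleSize <- function(x) nrow(x@members)

#' @rdname dailyQ90
#' @export
sampleMembers <- function(x) x@members
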