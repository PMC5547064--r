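# Seeded synthetic daily weather and GMST generator.
#
# The generator emulates the statistical structure the indices assume: a
# sinusoidal seasonal Tmax cycle, AR(1) daily anomalies (so multi-day
# exceedance runs occur at realistic rates), relative humidity generated
# conditionally on the temperature anomaly with a negative slope, an
# optional secular trend, and injectable multi-day heat-wave bumps with an
# optional humidity boost. All randomness flows from one seed; grid cells
# use substreams derived deterministically from (seed, cell index).

#' Create a synthetic weather configuration
#'
#' Defaults describe a warm, humid mid-latitude site: annual-mean Tmax
#' 22 °C with a 10 °C seasonal half-range (northern-summer peak), AR(1)
#' anomalies with lag-1 autocorrelation 0.7 and stationary SD 3 °C, mean
#' RHmin 60 % with SD 8 % and a −2 %/°C coupling to the temperature anomaly,
#' and no secular trend.
#'
#' @param years contiguous simulated years.
#' @param lats,lons grid coordinates (single site by default).
#' @param baseMeanC,latGradient,seasonalAmpC,ar1,dailySdC,tRhCoupling,rhMean,rhSd,trendPerDecade
#'   see [SynthConfig-class].
#' @param events data.frame of injected events (`year`, `startDay`,
#'   `duration`, `amplitude`, `rhBoost`); empty by default.
#' @param seed integer RNG seed.
#' @param calendar calendar name.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(years = 1981:2010, lats = 40, lons = 0,
                        baseMeanC = 22, latGradient = -0.4, seasonalAmpC = 10,
                        ar1 = 0.7, dailySdC = 3, tRhCoupling = -2,
                        rhMean = 60, rhSd = 8, trendPerDecade = 0,
                        events = NULL, seed = 1L, calendar = "standard") {
  if (is.null(events)) {
    events <- data.frame(year = integer(), startDay = integer(),
                         duration = integer(), amplitude = numeric(),
                         rhBoost = numeric())
  }
  new("SynthConfig",
      years = as.integer(years), lats = as.numeric(lats), lons = as.numeric(lons),
      baseMeanC = baseMeanC, latGradient = latGradient, seasonalAmpC = seasonalAmpC,
      ar1 = ar1, dailySdC = dailySdC, tRhCoupling = tRhCoupling,
      rhMean = rhMean, rhSd = rhSd, trendPerDecade = trendPerDecade,
      events = events, seed = as.integer(seed),
      calendar = match.arg(calendar, .CALENDARS))
}

# Deterministic substream seed for one grid cell; kept below 2^31.
.cellSeed <- function(seed, cell) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(cell) * 104729) %% 2147483629)
}

#' Seasonal mean Tmax cycle of a configuration
#'
#' @param config a [SynthConfig-class].
#' @param doy day-of-year vector.
#' @param yearLen length of the year on the configuration calendar.
#' @param lat latitude of the cell (defaults to the first grid latitude).
#' @return deterministic daily mean Tmax (°C), before anomalies and trend.
#' @export
seasonalCycle <- function(config, doy, yearLen = 365, lat = config@lats[1]) {
  base <- config@baseMeanC + config@latGradient * (lat - config@lats[1])
  peak <- 196 / 365 * yearLen   # northern mid-summer
  base + config@seasonalAmpC * cos(2 * pi * (doy - peak) / yearLen)
}

# Generate one cell. RNG draw order is fixed (all tmax innovations first,
# then all rh innovations) so that configs differing only in event rhBoost
# share the identical temperature realisation (common random numbers).
.generateCell <- function(config, lat, lon, seed, locationId) {
  cal <- config@calendar
  days <- do.call(rbind, lapply(config@years, .yearCalendar, calendar = cal))
  n <- nrow(days)
  yearLen <- .yearLength(days$year, cal)
  doy <- sequence(vapply(config@years, .yearLength, integer(1), calendar = cal))
  seas <- seasonalCycle(config, doy, yearLen = yearLen, lat = lat)
  trend <- config@trendPerDecade / 10 * (days$year - config@years[1])
  withr::with_seed(seed, {
    innovSd <- config@dailySdC * sqrt(1 - config@ar1^2)
    e <- rnorm(n, 0, innovSd)
    rhNoise <- rnorm(n, 0, config@rhSd)
    anom <- if (config@ar1 > 0) {
      a <- as.numeric(stats::filter(e, config@ar1, method = "recursive",
                                    init = rnorm(1, 0, config@dailySdC)))
      a
    } else e
  })
  tmax <- seas + trend + anom
  rh <- config@rhMean + config@tRhCoupling * anom + rhNoise
  ev <- config@events
  for (i in seq_len(nrow(ev))) {
    idx <- which(days$year == ev$year[i])[seq.int(ev$startDay[i],
                                                  ev$startDay[i] + ev$duration[i] - 1L)]
    tmax[idx] <- tmax[idx] + ev$amplitude[i]
    rh[idx] <- rh[idx] + ev$rhBoost[i]
  }
  rh <- pmin(pmax(rh, 0), 100)
  dailyClimateSeries(tmax = tmax, rhmin = rh,
                     year = days$year, month = days$month, day = days$day,
                     calendar = cal, locationId = locationId,
                     lat = lat, lon = lon)
}

#' Generate a synthetic daily series
#'
#' @param config a [SynthConfig-class] (single site: first lat/lon used).
#' @return a [DailyClimateSeries-class]; identical seed and configuration
#'   give bit-identical output.
#' @examples
#' s <- generateSeries(synthConfig(years = 1991:2000, seed = 42))
#' s
#' @export
generateSeries <- function(config) {
  validObject(config)
  .generateCell(config, config@lats[1], config@lons[1], config@seed, "synthetic-site")
}

#' Generate a synthetic climate grid
#'
#' One AR(1) substream per cell, derived deterministically from
#' `(seed, cell index)`; the annual-mean temperature falls off with latitude
#' at `latGradient` °C per degree.
#'
#' @param config a [SynthConfig-class] with grid `lats`/`lons`.
#' @return a [ClimateGrid-class].
#' @export
generateGrid <- function(config) {
  validObject(config)
  nLat <- length(config@lats); nLon <- length(config@lons)
  cells <- vector("list", nLat * nLon)
  for (j in seq_len(nLon)) {
    for (i in seq_len(nLat)) {
      cell <- (j - 1L) * nLat + i
      cells[[cell]] <- .generateCell(
        config, config@lats[i], config@lons[j], .cellSeed(config@seed, cell),
        sprintf("cell-%02d-%02d", i, j))
    }
  }
  climateGrid(config@lats, config@lons, cells)
}

#' Generate synthetic multi-run GMST anomaly trajectories
#'
#' Smooth scenario-like warming curves plus optional interannual noise,
#' emulating ensembles of global-mean surface temperature anomalies. Two
#' shapes are available: `"ramp"` rises linearly from 0 to `rampTo` °C over
#' the simulated span; `"stabilize"` saturates towards `capAt` °C.
#'
#' @param nRuns number of runs.
#' @param years simulated years.
#' @param scenario `"ramp"` or `"stabilize"`, recycled over runs.
#' @param rampTo final anomaly of the ramp (°C).
#' @param capAt asymptote of the stabilizing curve (°C).
#' @param noiseSd interannual noise SD (°C); 0 gives the deterministic curve.
#' @param seed integer seed.
#' @return data.frame with columns `run`, `year`, `anomaly`.
#' @examples
#' g <- generateGmstRuns(2, 1901:2100, noiseSd = 0, seed = 1)
#' range(g$anomaly)
#' @export
generateGmstRuns <- function(nRuns = 9, years = 1861:2100,
                             scenario = c("ramp"), rampTo = 4, capAt = 1.8,
                             noiseSd = 0.1, seed = 1L) {
  scen <- rep_len(scenario, nRuns)
  tfrac <- (years - years[1]) / (years[length(years)] - years[1])
  out <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    base <- switch(match.arg(scen[r], c("ramp", "stabilize")),
                   ramp = rampTo * tfrac,
                   stabilize = capAt * tanh(2.5 * tfrac))
    noise <- if (noiseSd > 0) {
      withr::with_seed(.cellSeed(seed, r), rnorm(length(years), 0, noiseSd))
    } else 0
    out[[r]] <- data.frame(run = sprintf("run%02d", r), year = years,
                           anomaly = base + noise)
  }
  do.call(rbind, out)
}

#' Fixture presets for the test suite
#'
#' `"site40y"`: a single warm humid site, 40 years (1976–2015).
#' `"grid8x8_150y"`: an 8 x 8 grid spanning latitudes 25–46°, 150 years
#' (1951–2100) with a 0.25 °C/decade warming trend.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a [SynthConfig-class].
#' @export
synthPreset <- function(name = c("site40y", "grid8x8_150y"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    site40y = synthConfig(years = 1976:2015, seed = seed),
    grid8x8_150y = synthConfig(years = 1951:2100,
                               lats = seq(25, 46, by = 3),
                               lons = seq(0, 21, by = 3),
                               trendPerDecade = 0.25, seed = seed))
}
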