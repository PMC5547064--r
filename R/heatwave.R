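# Heat-wave detection and annual indices: HWMId, AHWI, WSDI, AT_peak and the
# AT40C/AT55C danger flags.

#' Daily heat-wave magnitude
#'
#' The dimensionless daily magnitude
#' \deqn{M_d(T_d) = (T_d - T_{25}) / (T_{75} - T_{25})\ \mathrm{if}\ T_d > T_{25};
#'   \quad 0\ \mathrm{if}\ T_d \le T_{25},}
#' where \eqn{T_{25}} and \eqn{T_{75}} are the 25th/75th percentiles of the
#' reference-period annual maxima. A day at `t75` scores 1; magnitudes add up
#' over the consecutive days of a heat wave.
#'
#' @param td daily temperature (°C), vectorised; for the apparent index the
#'   argument is the apparent temperature on days where it exceeds `td`.
#' @param t25,t75 normalisation percentiles (°C), `t25 <= t75`.
#' @return dimensionless magnitudes (`NA` propagates; the degenerate case
#'   `t25 == t75` returns 0 at or below `t25` and `NA` with a warning above).
#' @examples
#' dailyMagnitude(c(30, 34, 38), t25 = 30, t75 = 34)  # 0 1 2
#' @export
dailyMagnitude <- function(td, t25, t75) {
  if (is.na(t25) || is.na(t75)) stop("t25/t75 must be finite")
  if (t25 > t75) stop("t25 must not exceed t75")
  if (t75 == t25) {
    out <- ifelse(is.na(td), NA_real_, ifelse(td <= t25, 0, NA_real_))
    if (any(is.na(out) & !is.na(td))) {
      warning("degenerate normalisation (t25 == t75): magnitude undefined above t25")
    }
    return(out)
  }
  ifelse(is.na(td), NA_real_, ifelse(td > t25, (td - t25) / (t75 - t25), 0))
}

#' Detect heat waves
#'
#' A heat wave is a run of at least `minDuration` (default 3) consecutive
#' days with `tmax` strictly above the calendar-day threshold. Missing
#' temperatures or thresholds terminate a run (missing is never exceedance).
#' Runs crossing Dec 31 are not split; an event belongs to the year of its
#' first day. When humidity is present, each event day also carries the
#' apparent temperature, and a heat wave is flagged humid if on at least one
#' of its days AT exceeds T.
#'
#' @param series a [DailyClimateSeries-class].
#' @param clim a [ThresholdClimatology-class] on the same calendar.
#' @param years optional integer vector: keep only events starting in these
#'   years.
#' @param strict use strict `>` exceedance (default TRUE).
#' @param minDuration minimum run length in days (default 3).
#' @param ahwiNormalization `"temperature"` (default) reuses the (t25, t75)
#'   pair for the apparent magnitudes; `"apparent"` uses the climatology's
#'   AT-based pair (requires `apparentNormalization = TRUE` upstream).
#' @param at optional precomputed apparent-temperature vector aligned with
#'   the series (computed from tmax/rhmin when NULL).
#' @return data.frame with one row per event: `year`, `startIndex` (into the
#'   series), `startMonth`, `startDay`, `duration`, `magnitudeSum` (HWMId
#'   contribution), `apparentMagnitudeSum` (AHWI contribution), `atPeak`,
#'   `humid`, and list columns `dailyTmax`, `dailyAt`, `dailyMagnitude`,
#'   `dailyApparentMagnitude`.
#' @export
detectHeatwaves <- function(series, clim, years = NULL, strict = TRUE,
                            minDuration = 3L,
                            ahwiNormalization = c("temperature", "apparent"),
                            at = NULL) {
  ahwiNormalization <- match.arg(ahwiNormalization)
  if (series@calendar != clim@calendar) {
    stop("series and climatology use different calendars")
  }
  thr <- clim@dailyQ90[.keyIndex(series@month, series@day, series@calendar)]
  exceed <- !is.na(series@tmax) & !is.na(thr) &
    (if (strict) series@tmax > thr else series@tmax >= thr)
  r <- rle(exceed)
  len <- r$lengths
  ends <- cumsum(len)
  starts <- ends - len + 1L
  keep <- r$values & len >= minDuration
  starts <- starts[keep]; lens <- len[keep]
  evYear <- series@year[starts]
  if (!is.null(years)) {
    sel <- evYear %in% years
    starts <- starts[sel]; lens <- lens[sel]; evYear <- evYear[sel]
  }
  nEv <- length(starts)
  if (is.null(at)) {
    at <- if (hasRhmin(series)) {
      apparentTemperatureC(series@tmax, series@rhmin)
    } else rep(NA_real_, length(series@tmax))
  }
  t25 <- clim@t25; t75 <- clim@t75
  a25 <- if (ahwiNormalization == "apparent") clim@at25 else t25
  a75 <- if (ahwiNormalization == "apparent") clim@at75 else t75
  if (ahwiNormalization == "apparent" && (is.na(a25) || is.na(a75))) {
    stop("climatology lacks the apparent normalisation pair; rebuild with apparentNormalization = TRUE")
  }
  dT <- dA <- mT <- mA <- vector("list", nEv)
  msum <- asum <- atp <- numeric(nEv)
  humid <- logical(nEv)
  for (i in seq_len(nEv)) {
    idx <- seq.int(starts[i], starts[i] + lens[i] - 1L)
    tv <- series@tmax[idx]
    av <- at[idx]
    eff <- ifelse(!is.na(av) & av > tv, av, tv)
    mT[[i]] <- dailyMagnitude(tv, t25, t75)
    mA[[i]] <- dailyMagnitude(eff, a25, a75)
    dT[[i]] <- tv; dA[[i]] <- av
    msum[i] <- sum(mT[[i]])
    asum[i] <- sum(mA[[i]])
    atp[i] <- if (all(is.na(av))) NA_real_ else max(av, na.rm = TRUE)
    humid[i] <- if (all(is.na(av))) NA else any(av > tv, na.rm = TRUE)
  }
  out <- data.frame(
    year = as.integer(evYear),
    startIndex = as.integer(starts),
    startMonth = series@month[starts],
    startDay = series@day[starts],
    duration = as.integer(lens),
    magnitudeSum = msum,
    apparentMagnitudeSum = asum,
    atPeak = atp,
    humid = humid
  )
  out$dailyTmax <- dT
  out$dailyAt <- dA
  out$dailyMagnitude <- mT
  out$dailyApparentMagnitude <- mA
  out
}

#' Annual heat-wave indices from an event table
#'
#' `hwmid()` is the maximum over a year's heat waves of the summed daily
#' magnitudes (0 with no event). `ahwi()` is the analogous maximum with the
#' apparent temperature substituted for days on which AT > T; it requires
#' humidity and always satisfies `ahwi >= hwmid` under the shared
#' temperature-based normalisation. `wsdi()` is the duration (days) of the
#' year's maximum-magnitude heat wave (0 with no event).
#' `atPeakAndFlags()` returns the maximum AT over all heat-wave days plus the
#' binary danger flags `at40c = 1` if `atPeak > 40` °C and `at55c = 1` if
#' `atPeak > 55` °C (strict comparisons; 0 with no event, `atPeak` then `NA`).
#'
#' @param events event table from [detectHeatwaves()], restricted to one year.
#' @return `hwmid`/`ahwi`: dimensionless scalar; `wsdi`: integer days;
#'   `atPeakAndFlags`: list with `atPeak`, `at40c`, `at55c`.
#' @export
hwmid <- function(events) {
  if (nrow(events) == 0L) return(0)
  max(events$magnitudeSum)
}

#' @rdname hwmid
#' @export
ahwi <- function(events) {
  if (nrow(events) == 0L) return(0)
  if (all(is.na(unlist(events$dailyAt)))) {
    stop("no apparent temperature available (rhmin absent); use hwmid() for the temperature-only index")
  }
  max(events$apparentMagnitudeSum)
}

#' @rdname hwmid
#' @export
wsdi <- function(events) {
  if (nrow(events) == 0L) return(0L)
  events$duration[which.max(events$magnitudeSum)]
}

#' @rdname hwmid
#' @export
atPeakAndFlags <- function(events) {
  if (nrow(events) == 0L || all(is.na(events$atPeak))) {
    return(list(atPeak = NA_real_, at40c = 0L, at55c = 0L))
  }
  p <- max(events$atPeak, na.rm = TRUE)
  list(atPeak = p, at40c = as.integer(p > 40), at55c = as.integer(p > 55))
}

# One year's annual record from a precomputed full-series event table.
.annualRecord <- function(events, y) {
  ev <- events[events$year == y, , drop = FALSE]
  pk <- atPeakAndFlags(ev)
  a <- if (nrow(ev) && !all(is.na(unlist(ev$dailyAt)))) ahwi(ev) else {
    if (nrow(ev) == 0L) 0 else NA_real_
  }
  data.frame(year = y, hwmid = hwmid(ev), ahwi = a, wsdi = wsdi(ev),
             atPeak = pk$atPeak, at40c = pk$at40c, at55c = pk$at55c,
             nEvents = nrow(ev))
}

#' Annual index records for a series
#'
#' Detects heat waves over the whole series and reduces them to one record
#' per year: HWMId, AHWI, WSDI, AT_peak, the AT40C/AT55C flags and the event
#' count. With `inbaseCorrection = TRUE`, the reference-period years are
#' replaced by ETCCDI-style bootstrap-corrected values (see
#' [inbaseCorrectedIndices()]); out-of-base years are untouched.
#'
#' @inheritParams detectHeatwaves
#' @param years years to report (default: all years in the series).
#' @param inbaseCorrection apply the in-base bootstrap correction.
#' @param ... passed to [detectHeatwaves()] / [inbaseCorrectedIndices()].
#' @return data.frame with columns `year`, `hwmid`, `ahwi`, `wsdi`,
#'   `atPeak`, `at40c`, `at55c`, `nEvents`. When humidity is absent the
#'   AHWI/AT columns are `NA`/0.
#' @examples
#' s <- generateSeries(synthConfig(years = 1981:2015, seed = 7))
#' clim <- thresholdClimatology(s, c(1981L, 2010L))
#' head(annualIndices(s, clim))
#' @export
annualIndices <- function(series, clim, years = NULL,
                          inbaseCorrection = FALSE, strict = TRUE,
                          minDuration = 3L, ...) {
  if (is.null(years)) years <- seriesYears(series)
  events <- detectHeatwaves(series, clim, strict = strict,
                            minDuration = minDuration, ...)
  rec <- do.call(rbind, lapply(years, function(y) .annualRecord(events, y)))
  if (inbaseCorrection) {
    corr <- inbaseCorrectedIndices(series, clim@referencePeriod,
                                   windowDays = clim@windowDays,
                                   quantileProb = clim@quantileProb,
                                   strict = strict, minDuration = minDuration)
    ib <- match(corr$year, rec$year)
    keep <- !is.na(ib)
    for (colname in c("hwmid", "ahwi", "wsdi", "atPeak", "nEvents")) {
      rec[[colname]][ib[keep]] <- corr[[colname]][keep]
    }
    rec$at40c[ib[keep]] <- as.integer(!is.na(corr$atPeak[keep]) & corr$atPeak[keep] > 40)
    rec$at55c[ib[keep]] <- as.integer(!is.na(corr$atPeak[keep]) & corr$atPeak[keep] > 55)
  }
  rec
}
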