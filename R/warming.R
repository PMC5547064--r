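# Warming-level selection and empirical hazard probabilities.

#' Global-mean temperature anomaly series
#'
#' Area-weighted (cosine-of-latitude) global mean of an annual-mean
#' temperature field, expressed as an anomaly relative to the mean of the
#' baseline period. Missing cells are handled by renormalising the weights
#' over available cells; a warning is raised when weighted coverage drops
#' below 95 %.
#'
#' @param annualMeans numeric array `[year, lat, lon]` of annual mean
#'   temperatures (°C); `dimnames[[1]]` must give the years.
#' @param lats latitude vector (degrees), matching `dim(annualMeans)[2]`.
#' @param baselinePeriod integer `c(first, last)` baseline years
#'   (default 1861–1880).
#' @return data.frame with columns `year` and `anomaly` (°C).
#' @export
globalMeanAnomaly <- function(annualMeans, lats, baselinePeriod = c(1861L, 1880L)) {
  if (is.null(dimnames(annualMeans)[[1]])) {
    stop("annualMeans must carry years as dimnames[[1]]")
  }
  years <- as.integer(dimnames(annualMeans)[[1]])
  if (length(lats) != dim(annualMeans)[2]) {
    stop("lats length must match the second dimension of annualMeans")
  }
  w <- cos(lats * pi / 180)
  wmat <- matrix(rep(w, times = dim(annualMeans)[3]),
                 nrow = length(lats))
  totalW <- sum(wmat)
  gm <- vapply(seq_along(years), function(i) {
    f <- annualMeans[i, , , drop = TRUE]
    f <- matrix(f, nrow = length(lats))
    ok <- !is.na(f)
    if (!any(ok)) return(NA_real_)
    if (sum(wmat[ok]) < 0.95 * totalW) {
      warning(sprintf("year %d: weighted coverage below 95%%", years[i]))
    }
    sum(f[ok] * wmat[ok]) / sum(wmat[ok])
  }, numeric(1))
  base <- years >= baselinePeriod[1] & years <= baselinePeriod[2]
  if (!any(base)) stop("no baseline years present in annualMeans")
  data.frame(year = years, anomaly = gm - mean(gm[base], na.rm = TRUE))
}

#' Select model-years at a warming level
#'
#' Pools, across runs and scenarios, all (run, year) pairs whose global-mean
#' anomaly lies within the closed window
#' `[level - halfwidth, level + halfwidth]` — e.g. 1.4–1.6 °C for the 1.5 °C
#' level. Every member-year carries equal weight.
#'
#' @param gmst data.frame with columns `run`, `year`, `anomaly` (°C relative
#'   to the baseline).
#' @param level nominal warming level (°C).
#' @param halfwidth window half-width (°C, default 0.1).
#' @param baselinePeriod recorded baseline years (metadata).
#' @return a [WarmingLevelSample-class].
#' @export
selectWarmingYears <- function(gmst, level, halfwidth = 0.1,
                               baselinePeriod = c(1861L, 1880L)) {
  stopifnot(all(c("run", "year", "anomaly") %in% names(gmst)))
  sel <- !is.na(gmst$anomaly) &
    gmst$anomaly >= level - halfwidth & gmst$anomaly <= level + halfwidth
  members <- gmst[sel, c("run", "year", "anomaly")]
  if (nrow(members) == 0L) {
    nearest <- gmst[order(abs(gmst$anomaly - level)), ]
    stop(sprintf(
      "no model-years within %.2f ± %.2f °C; nearest anomalies: %s",
      level, halfwidth,
      paste(sprintf("%.2f (run %s, %d)", head(nearest$anomaly, 3),
                    head(nearest$run, 3), head(nearest$year, 3)),
            collapse = ", ")))
  }
  rownames(members) <- NULL
  new("WarmingLevelSample", level = level, halfwidth = halfwidth,
      members = members, baselinePeriod = as.integer(baselinePeriod))
}

#' Empirical exceedance probability per location
#'
#' The empirical probability of an event is the count of member-years in
#' which it occurs divided by the count of usable member-years (its
#' reciprocal is the average return period). Missing event values are
#' excluded per location with count bookkeeping; a location with zero usable
#' trials gets `NA`.
#'
#' @param binaryField data.frame with columns `run`, `year`, `location`,
#'   `event` (0/1/NA), one row per member-year and location.
#' @param sample a [WarmingLevelSample-class].
#' @return data.frame with columns `location`, `probability`, `nEvents`,
#'   `nTrials`.
#' @export
empiricalProbability <- function(binaryField, sample) {
  stopifnot(all(c("run", "year", "location", "event") %in% names(binaryField)))
  m <- sample@members
  key <- paste(binaryField$run, binaryField$year, sep = "\r")
  mkey <- paste(m$run, m$year, sep = "\r")
  bf <- binaryField[key %in% mkey, , drop = FALSE]
  locs <- unique(binaryField$location)
  res <- do.call(rbind, lapply(locs, function(l) {
    ev <- bf$event[bf$location == l]
    n <- sum(!is.na(ev))
    k <- sum(ev == 1, na.rm = TRUE)
    data.frame(location = l, probability = if (n) k / n else NA_real_,
               nEvents = k, nTrials = n)
  }))
  rownames(res) <- NULL
  res
}

# "HWMId>60" / "AHWI>60" / "AT40C" / "AT_peak>=40" -> list(var, cmp, thr)
.parseDefinition <- function(def) {
  d <- gsub(" ", "", def)
  if (toupper(d) == "AT40C") return(list(var = "atPeak", cmp = ">", thr = 40))
  if (toupper(d) == "AT55C") return(list(var = "atPeak", cmp = ">", thr = 55))
  m <- regmatches(d, regexec("^([A-Za-z_]+)(>=|<=|>|<)([-0-9.]+)$", d))[[1]]
  if (length(m) != 4L) stop(sprintf("cannot parse event definition '%s'", def))
  var <- switch(tolower(m[2]),
    hwmid = "hwmid", ahwi = "ahwi", wsdi = "wsdi",
    at_peak = "atPeak", atpeak = "atPeak",
    stop(sprintf("unknown index '%s' in event definition '%s'", m[2], def)))
  list(var = var, cmp = m[3], thr = as.numeric(m[4]))
}

#' Hazard exceedance probability maps
#'
#' Applies one or more event definitions (e.g. `"HWMId>60"`, `"AHWI>60"`,
#' `"AT40C"`, `"AT_peak>=40"`) to annual index records and delegates each to
#' [empiricalProbability()]. The named flags AT40C/AT55C use the strict
#' `atPeak > 40` / `> 55` comparisons; explicit expressions choose their own
#' comparator.
#'
#' @param indices data.frame of annual records with columns `run`, `year`,
#'   `location` and the index columns (`hwmid`, `ahwi`, `wsdi`, `atPeak`).
#' @param sample a [WarmingLevelSample-class].
#' @param definitions character vector of event definitions.
#' @return named list (one element per definition) of probability
#'   data.frames as returned by [empiricalProbability()].
#' @export
hazardProbabilityMaps <- function(indices, sample,
                                  definitions = c("HWMId>60", "AHWI>60",
                                                  "AT40C", "AT55C")) {
  out <- lapply(definitions, function(def) {
    p <- .parseDefinition(def)
    if (!p$var %in% names(indices)) {
      stop(sprintf("index column '%s' absent from the records", p$var))
    }
    v <- indices[[p$var]]
    ev <- switch(p$cmp,
                 ">" = v > p$thr, ">=" = v >= p$thr,
                 "<" = v < p$thr, "<=" = v <= p$thr)
    bf <- data.frame(run = indices$run, year = indices$year,
                     location = indices$location, event = as.integer(ev))
    empiricalProbability(bf, sample)
  })
  names(out) <- definitions
  out
}

#' Decadal median of global-mean anomalies
#'
#' Display summary of GMST trajectories: the median anomaly per decade,
#' optionally per scenario/run grouping.
#'
#' @param gmst data.frame with `year`, `anomaly` and optionally a grouping
#'   column named by `by`.
#' @param by optional grouping column name (e.g. `"scenario"`).
#' @return data.frame of decade starts and median anomalies.
#' @export
decadalMedianGmst <- function(gmst, by = NULL) {
  dec <- (gmst$year %/% 10L) * 10L
  if (is.null(by)) {
    agg <- aggregate(list(anomaly = gmst$anomaly), list(decade = dec), median)
  } else {
    agg <- aggregate(list(anomaly = gmst$anomaly),
                     list(decade = dec, group = gmst[[by]]), median)
  }
  agg
}
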