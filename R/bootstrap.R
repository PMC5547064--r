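# ETCCDI-style in-base bootstrap bias correction.
#
# Threshold-relative indices are biased inside the threshold reference
# period: each in-base year contributes to its own threshold, producing a
# discontinuity between in-base and out-of-base estimates. The standard
# resampling remedy: for in-base year y, remove y from the base and, for
# each remaining year z, rebuild a full-size surrogate base with z counted
# twice; evaluate the index for y against each surrogate climatology and
# average the 29 estimates. Daily thresholds and the t25/t75 pair are
# recomputed jointly for every surrogate.

# Lean annual record used on the bootstrap hot path: identical semantics to
# detectHeatwaves() + the annual reducers, restricted to runs starting in
# year y (the scan covers y-1..y+1 so runs crossing either year boundary
# are attributed correctly).
.annualStatsFast <- function(series, thr, keyIdxAll, atAll, y, t25, t75,
                             strict, minDuration) {
  idx <- which(series@year >= y - 1L & series@year <= y + 1L)
  tv <- series@tmax[idx]
  th <- thr[keyIdxAll[idx]]
  ex <- !is.na(tv) & !is.na(th) & (if (strict) tv > th else tv >= th)
  r <- rle(ex)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= minDuration &
                  series@year[idx][starts] == y)
  if (!length(keep)) {
    return(c(hwmid = 0, ahwi = 0, wsdi = 0, atPeak = NA_real_, nEvents = 0))
  }
  av <- atAll[idx]
  hasAt <- !all(is.na(av))
  msum <- asum <- atp <- numeric(length(keep))
  dur <- r$lengths[keep]
  for (i in seq_along(keep)) {
    sel <- seq.int(starts[keep[i]], ends[keep[i]])
    t <- tv[sel]
    a <- av[sel]
    eff <- ifelse(!is.na(a) & a > t, a, t)
    msum[i] <- sum(dailyMagnitude(t, t25, t75))
    asum[i] <- sum(dailyMagnitude(eff, t25, t75))
    atp[i] <- if (all(is.na(a))) NA_real_ else max(a, na.rm = TRUE)
  }
  c(hwmid = max(msum),
    ahwi = if (hasAt) max(asum) else NA_real_,
    wsdi = dur[which.max(msum)],
    atPeak = if (all(is.na(atp))) NA_real_ else max(atp, na.rm = TRUE),
    nEvents = length(keep))
}

#' In-base bootstrap-corrected indices
#'
#' For each year of the reference period, evaluates the annual indices
#' against the 29 leave-one-out/duplicate-one surrogate climatologies and
#' returns the per-year mean. Out-of-base years are unaffected by
#' construction. A custom `indexFun` may replace the default annual
#' heat-wave record (HWMId, AHWI, WSDI, AT_peak, event count).
#'
#' @param series a [DailyClimateSeries-class] fully covering the reference
#'   period.
#' @param referencePeriod integer `c(first, last)`; at least 3 years.
#' @param windowDays,quantileProb,minFrac threshold parameters as in
#'   [dailyThreshold()].
#' @param indexFun optional `function(series, clim, year)` returning a named
#'   numeric vector, evaluated against every surrogate climatology.
#' @param strict,minDuration detection parameters for the default indices.
#' @return data.frame with column `year` and one column per index, each the
#'   mean over the 29 surrogate estimates (for `atPeak`, over surrogates
#'   with at least one event).
#' @examples
#' s <- generateSeries(synthConfig(years = 1991:2000, seed = 2))
#' head(inbaseCorrectedIndices(s, c(1991L, 2000L)), 3)
#' @export
inbaseCorrectedIndices <- function(series, referencePeriod,
                                   windowDays = 31L, quantileProb = 0.9,
                                   minFrac = 0.8, indexFun = NULL,
                                   strict = TRUE, minDuration = 3L) {
  refYears <- .checkReference(series, referencePeriod)
  if (length(refYears) < 3L) {
    stop("the bootstrap correction is undefined for reference periods shorter than 3 years")
  }
  prep <- .climPrep(series, refYears, windowDays)
  keyIdxAll <- prep$keyIdx
  atAll <- if (hasRhmin(series)) {
    apparentTemperatureC(series@tmax, series@rhmin)
  } else rep(NA_real_, length(series@tmax))
  out <- vector("list", length(refYears))
  for (i in seq_along(refYears)) {
    y <- refYears[i]
    others <- refYears[refYears != y]
    idxOthers <- match(others, refYears)
    thrMat <- .cppSurrogateThresholds(prep$values, prep$exists, prep$windows,
                                      idxOthers - 1L, quantileProb, minFrac)
    est <- NULL
    for (m in seq_along(others)) {
      am <- prep$annualMax[c(idxOthers, idxOthers[m])]
      am <- am[!is.na(am)]
      tq <- quantile(am, c(0.25, 0.75), type = 7, names = FALSE)
      v <- if (is.null(indexFun)) {
        .annualStatsFast(series, thrMat[, m], keyIdxAll, atAll, y,
                         tq[1], tq[2], strict, minDuration)
      } else {
        clim <- .climFromParts(thrMat[, m], tq, referencePeriod, windowDays,
                               quantileProb, prep$calendar)
        indexFun(series, clim, y)
      }
      if (is.null(est)) {
        est <- matrix(NA_real_, length(others), length(v),
                      dimnames = list(NULL, names(v)))
      }
      est[m, ] <- as.numeric(v)
    }
    out[[i]] <- colMeans(est, na.rm = TRUE)
  }
  res <- as.data.frame(do.call(rbind, out))
  res[vapply(res, function(col) all(is.nan(col) | is.na(col)), logical(1))] <- NA_real_
  res[] <- lapply(res, function(col) { col[is.nan(col)] <- NA_real_; col })
  cbind(year = refYears, res)
}
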