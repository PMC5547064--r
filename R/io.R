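# Plain-text I/O and regridding.
#
# Series, grids and threshold climatologies are stored as CSV with a small
# block of "# key: value" metadata lines (calendar, coordinates, units,
# reference period), so files remain self-describing and round-trip exactly.
# Internally temperatures are °C and humidity is % in [0, 100]; Kelvin and
# fractional humidity are converted at the read boundary.

.writeMeta <- function(con, meta) {
  writeLines(sprintf("# %s: %s", names(meta), vapply(meta, as.character, "")), con)
}

.readMeta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- regmatches(lines, regexec("^# ([^:]+): (.*)$", lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  stats::setNames(as.list(vals), keys)
}

.convertUnits <- function(df, tempUnit, rhUnit) {
  tempUnit <- match.arg(tempUnit, c("C", "K"))
  rhUnit <- match.arg(rhUnit, c("percent", "fraction"))
  if (tempUnit == "K") df$tmax <- df$tmax - 273.15
  if (rhUnit == "fraction" && !is.null(df$rhmin)) df$rhmin <- df$rhmin * 100
  df
}

#' Read and write daily series as CSV
#'
#' The format is a CSV with columns `year,month,day,tmax[,rhmin]` preceded by
#' `# key: value` metadata lines (calendar, location, lat, lon).
#'
#' @param series a [DailyClimateSeries-class].
#' @param path file path.
#' @param tempUnit `"C"` (default) or `"K"` — unit of `tmax` in the file.
#' @param rhUnit `"percent"` (default) or `"fraction"`.
#' @return `readSeriesCsv` returns a [DailyClimateSeries-class];
#'   `writeSeriesCsv` returns `path` invisibly.
#' @export
writeSeriesCsv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .writeMeta(con, list(format = "humidheat-series v1",
                       calendar = series@calendar,
                       location = series@locationId,
                       lat = series@lat, lon = series@lon))
  utils::write.csv(as.data.frame(series), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSeriesCsv
#' @export
readSeriesCsv <- function(path, tempUnit = "C", rhUnit = "percent") {
  meta <- .readMeta(path)
  if (is.null(meta$calendar)) stop("missing '# calendar:' metadata line")
  if (!(meta$calendar %in% .CALENDARS)) {
    stop(sprintf("unknown calendar '%s' in %s", meta$calendar, path))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("year", "month", "day", "tmax") %in% names(df))) {
    stop("series CSV needs columns year, month, day, tmax")
  }
  df <- .convertUnits(df, tempUnit, rhUnit)
  dailyClimateSeries(tmax = df$tmax, rhmin = df$rhmin,
                     year = df$year, month = df$month, day = df$day,
                     calendar = meta$calendar,
                     locationId = if (is.null(meta$location)) "site" else meta$location,
                     lat = as.numeric(meta$lat), lon = as.numeric(meta$lon))
}

#' Read and write climate grids as long-format CSV
#'
#' Columns `lat,lon,year,month,day,tmax[,rhmin]` with metadata header lines.
#' Temperature and humidity units are converted at read time via `tempUnit`
#' and `rhUnit`.
#'
#' @param grid a [ClimateGrid-class].
#' @inheritParams writeSeriesCsv
#' @return `readGridCsv` returns a [ClimateGrid-class].
#' @export
writeGridCsv <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cal <- grid@series[[1]]@calendar
  .writeMeta(con, list(format = "humidheat-grid v1", calendar = cal))
  coords <- gridCoords(grid)
  parts <- lapply(seq_along(grid@series), function(i) {
    df <- as.data.frame(grid@series[[i]])
    cbind(lat = coords$lat[i], lon = coords$lon[i], df)
  })
  utils::write.csv(do.call(rbind, parts), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGridCsv
#' @export
readGridCsv <- function(path, tempUnit = "C", rhUnit = "percent") {
  meta <- .readMeta(path)
  if (is.null(meta$calendar)) stop("missing '# calendar:' metadata line")
  if (!(meta$calendar %in% .CALENDARS)) {
    stop(sprintf("unknown calendar '%s' in %s", meta$calendar, path))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("lat", "lon", "year", "month", "day", "tmax")
  if (!all(need %in% names(df))) {
    stop(sprintf("grid CSV needs columns %s", paste(need, collapse = ", ")))
  }
  df <- .convertUnits(df, tempUnit, rhUnit)
  lats <- sort(unique(df$lat)); lons <- sort(unique(df$lon))
  cells <- vector("list", length(lats) * length(lons))
  for (j in seq_along(lons)) {
    for (i in seq_along(lats)) {
      sub <- df[df$lat == lats[i] & df$lon == lons[j], , drop = FALSE]
      cells[[(j - 1L) * length(lats) + i]] <- dailyClimateSeries(
        tmax = sub$tmax, rhmin = sub$rhmin,
        year = sub$year, month = sub$month, day = sub$day,
        calendar = meta$calendar,
        locationId = sprintf("cell-%g-%g", lats[i], lons[j]),
        lat = lats[i], lon = lons[j])
    }
  }
  climateGrid(lats, lons, cells)
}

#' @rdname writeGridCsv
#' @param variable unused placeholder kept for interface stability.
#' @export
readDailyGrid <- function(path, tempUnit = "C", rhUnit = "percent", variable = NULL) {
  readGridCsv(path, tempUnit = tempUnit, rhUnit = rhUnit)
}

#' Read and write a threshold climatology as CSV
#'
#' Columns `month,day,q90`; the normalisation pair, reference period, window,
#' quantile and calendar travel as metadata lines (provenance for downstream
#' runs).
#'
#' @param clim a [ThresholdClimatology-class].
#' @param path file path.
#' @return `readClimatologyCsv` returns a [ThresholdClimatology-class].
#' @export
writeClimatologyCsv <- function(clim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .writeMeta(con, list(format = "humidheat-climatology v1",
                       calendar = clim@calendar,
                       reference = paste(clim@referencePeriod, collapse = "-"),
                       window_days = clim@windowDays,
                       quantile = clim@quantileProb,
                       t25 = sprintf("%.10g", clim@t25),
                       t75 = sprintf("%.10g", clim@t75)))
  keys <- calendarKeys(clim@calendar)
  utils::write.csv(data.frame(month = keys$month, day = keys$day,
                              q90 = clim@dailyQ90),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeClimatologyCsv
#' @export
readClimatologyCsv <- function(path) {
  meta <- .readMeta(path)
  df <- utils::read.csv(path, comment.char = "#")
  ref <- as.integer(strsplit(meta$reference, "-")[[1]])
  thr <- df$q90
  names(thr) <- sprintf("%02d-%02d", df$month, df$day)
  new("ThresholdClimatology",
      dailyQ90 = thr, t25 = as.numeric(meta$t25), t75 = as.numeric(meta$t75),
      at25 = NA_real_, at75 = NA_real_,
      referencePeriod = ref, windowDays = as.integer(meta$window_days),
      quantileProb = as.numeric(meta$quantile), calendar = meta$calendar)
}

#' Write a per-event table
#'
#' Flattens a [detectHeatwaves()] event table (dropping the per-day list
#' columns) to CSV: start date, duration, HWMId and AHWI contributions, AT
#' peak and the humid flag — the per-event quantities reported alongside
#' single-site series.
#'
#' @param events event table from [detectHeatwaves()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(events, path) {
  flat <- events[, c("year", "startMonth", "startDay", "duration",
                     "magnitudeSum", "apparentMagnitudeSum", "atPeak", "humid")]
  names(flat) <- c("year", "start_month", "start_day", "duration_days",
                   "hwmid_contribution", "ahwi_contribution", "at_peak_c", "humid")
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse sub-daily records to daily extremes
#'
#' Helper for 6-hourly style inputs: groups records by UTC calendar date and
#' returns the daily maximum temperature and daily minimum relative humidity.
#'
#' @param time `POSIXct` timestamps (UTC).
#' @param temp temperatures (°C).
#' @param rh optional relative humidity (%).
#' @return data.frame with `year`, `month`, `day`, `tmax` and (if given)
#'   `rhmin`.
#' @export
dailyExtremes <- function(time, temp, rh = NULL) {
  date <- as.Date(time, tz = "UTC")
  tmax <- tapply(temp, date, max, na.rm = TRUE)
  d <- as.Date(names(tmax))
  lt <- as.POSIXlt(d)
  out <- data.frame(year = lt$year + 1900L, month = lt$mon + 1L, day = lt$mday,
                    tmax = as.numeric(tmax))
  if (!is.null(rh)) out$rhmin <- as.numeric(tapply(rh, date, min, na.rm = TRUE))
  out
}

#' Bilinear regridding on rectilinear latitude-longitude grids
#'
#' Standard bilinear interpolation of a field from one rectilinear grid to
#' another. Longitudes are normalised to \[0, 360) and interpolation wraps
#' across the dateline when `wrapLon = TRUE`. Target points outside the
#' source latitude hull (or longitude hull when not wrapping) use
#' nearest-edge extrapolation and are flagged in the `"extrapolated"`
#' attribute of the result.
#'
#' @param field numeric matrix `[lat, lon]`.
#' @param lats,lons ascending source coordinates matching `dim(field)`.
#' @param targetLats,targetLons target coordinates.
#' @param wrapLon treat longitude as periodic (default TRUE).
#' @return matrix `[targetLat, targetLon]` with a logical
#'   `"extrapolated"` attribute of the same shape.
#' @export
bilinearRegrid <- function(field, lats, lons, targetLats, targetLons,
                           wrapLon = TRUE) {
  if (!is.matrix(field) || nrow(field) != length(lats) || ncol(field) != length(lons)) {
    stop("field must be a [lat, lon] matrix matching the coordinate vectors (rectilinear grid)")
  }
  if (is.unsorted(lats, strictly = TRUE)) stop("lats must be strictly ascending")
  norm <- function(x) ((x %% 360) + 360) %% 360
  lonsN <- norm(lons)
  o <- order(lonsN)
  lonsN <- lonsN[o]
  field <- field[, o, drop = FALSE]
  if (is.unsorted(lonsN, strictly = TRUE)) stop("longitudes do not form a rectilinear axis")
  if (wrapLon) {
    lonsE <- c(lonsN, lonsN[1] + 360)
    fieldE <- cbind(field, field[, 1])
  } else {
    lonsE <- lonsN
    fieldE <- field
  }
  tl <- norm(targetLons)
  out <- matrix(NA_real_, length(targetLats), length(targetLons))
  extra <- matrix(FALSE, length(targetLats), length(targetLons))
  interp1idx <- function(x, grid) {
    i <- findInterval(x, grid)
    i <- pmin(pmax(i, 1L), length(grid) - 1L)
    w <- (x - grid[i]) / (grid[i + 1L] - grid[i])
    list(i = i, w = pmin(pmax(w, 0), 1),
         extrap = x < grid[1] | x > grid[length(grid)])
  }
  la <- interp1idx(targetLats, lats)
  # wrapping target longitudes below the first source longitude up one period
  tlAdj <- ifelse(wrapLon & tl < lonsE[1], tl + 360, tl)
  lo <- interp1idx(tlAdj, lonsE)
  for (j in seq_along(targetLons)) {
    f00 <- fieldE[la$i, lo$i[j]]
    f10 <- fieldE[la$i + 1L, lo$i[j]]
    f01 <- fieldE[la$i, lo$i[j] + 1L]
    f11 <- fieldE[la$i + 1L, lo$i[j] + 1L]
    wl <- la$w
    out[, j] <- (1 - lo$w[j]) * ((1 - wl) * f00 + wl * f10) +
      lo$w[j] * ((1 - wl) * f01 + wl * f11)
    extra[, j] <- la$extrap | lo$extrap[j]
  }
  attr(out, "extrapolated") <- extra
  out
}

#' Load a synthetic weather configuration from YAML
#'
#' Reads the fields of [synthConfig()] from a YAML mapping (unknown keys are
#' rejected); `events` may be given as a list of mappings.
#'
#' @param path YAML file path.
#' @return a [SynthConfig-class].
#' @export
synthConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(synthConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(y$events)) {
    y$events <- do.call(rbind, lapply(y$events, as.data.frame))
  }
  if (!is.null(y$years) && length(y$years) == 2L) {
    y$years <- seq.int(y$years[1], y$years[2])
  }
  do.call(synthConfig, y)
}
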