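#' Annual index records for every cell of a grid
#'
#' Builds a [ThresholdClimatology-class] per cell from the shared reference
#' period and reduces each cell's series to annual records, returned in the
#' long layout that [hazardProbabilityMaps()] consumes (`location` is the
#' cell's `"lat,lon"` label, `run` a constant label for single-run grids).
#'
#' @param grid a [ClimateGrid-class].
#' @param referencePeriod integer `c(first, last)` reference years.
#' @param run run label attached to every record (default `"run01"`).
#' @param ... passed to [thresholdClimatology()] and [annualIndices()]
#'   (e.g. `inbaseCorrection`, `windowDays`, `quantileProb`).
#' @return data.frame of annual records with `run`, `location`, `lat`,
#'   `lon` prepended.
#' @export
gridAnnualIndices <- function(grid, referencePeriod, run = "run01", ...) {
  dots <- list(...)
  climArgs <- dots[names(dots) %in% names(formals(thresholdClimatology))]
  idxArgs <- dots[names(dots) %in% names(formals(annualIndices))]
  coords <- gridCoords(grid)
  parts <- lapply(seq_along(grid@series), function(i) {
    s <- grid@series[[i]]
    clim <- do.call(thresholdClimatology,
                    c(list(series = s, referencePeriod = referencePeriod), climArgs))
    rec <- do.call(annualIndices, c(list(series = s, clim = clim), idxArgs))
    cbind(run = run,
          location = sprintf("%g,%g", coords$lat[i], coords$lon[i]),
          lat = coords$lat[i], lon = coords$lon[i], rec)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
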