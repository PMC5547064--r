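#' Heat-index regression coefficients
#'
#' Coefficients of the NOAA heat-index (apparent temperature) regression,
#' which operates on temperature in °F and relative humidity in %:
#' \deqn{AT = c_1 + c_2 T + c_3 R + c_4 T R + c_5 T^2 + c_6 R^2 +
#'       c_7 T^2 R + c_8 T R^2 + c_9 T^2 R^2.}
#'
#' Defaults are the NOAA values. Note on `c9`: a transcription printing
#' `-0.199e-6` circulates in the literature; with it the regression returns
#' ~177 °F at (90 °F, 70 %) instead of ~106 °F. The NOAA source value
#' `-1.99e-6` is the default here, and `c9` is configurable for comparison.
#'
#' @param c1,c2,c3,c4,c5,c6,c7,c8,c9 regression coefficients.
#' @return named numeric vector of length 9.
#' @export
heatIndexCoefficients <- function(c1 = -42.379, c2 = 2.04901523, c3 = 10.14333127,
                                  c4 = -0.22475541, c5 = -6.83783e-3,
                                  c6 = -5.481717e-2, c7 = 1.22874e-3,
                                  c8 = 8.5282e-4, c9 = -1.99e-6) {
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, c7 = c7, c8 = c8, c9 = c9)
}

#' NOAA heat index in °F
#'
#' Element-wise apparent temperature following the NOAA fact-sheet algorithm:
#' \enumerate{
#'   \item the simple formula
#'     `0.5 * (T + 61 + (T - 68) * 1.2 + R * 0.094)` is computed; if its
#'     average with `T` is below 80 °F it is returned as-is;
#'   \item otherwise the full regression (see
#'     [heatIndexCoefficients()]) applies, with two adjustments:
#'   \item for `R < 13` and `80 <= T <= 112`, subtract
#'     `((13 - R) / 4) * sqrt((17 - abs(T - 95)) / 17)`;
#'   \item for `R > 85` and `80 <= T <= 87`, add
#'     `((R - 85) / 10) * ((87 - T) / 2)`.
#' }
#' Missing inputs propagate as `NA`; no clamping is applied at high values
#' (a warning is raised for inputs above 130 °F, beyond the chart's range).
#'
#' @param tempF dry-bulb temperature, °F (scalar or vector).
#' @param rh relative humidity in % within \[0, 100\] (recycled).
#' @param coef coefficient vector from [heatIndexCoefficients()].
#' @return apparent temperature, °F.
#' @examples
#' heatIndexF(80, 0)   # 77.7, simple branch
#' heatIndexF(96, 65)  # ~121, full regression
#' @export
heatIndexF <- function(tempF, rh, coef = heatIndexCoefficients()) {
  n <- max(length(tempF), length(rh))
  t <- rep_len(as.numeric(tempF), n)
  r <- rep_len(as.numeric(rh), n)
  bad <- !is.na(r) & (r < 0 | r > 100)
  if (any(bad)) {
    stop(sprintf("relative humidity outside [0, 100]: e.g. %g", r[which(bad)[1]]))
  }
  if (any(t > 130, na.rm = TRUE)) {
    warning("temperatures above 130 °F: heat index reported as computed, outside the chart's validity range")
  }
  simple <- 0.5 * (t + 61 + (t - 68) * 1.2 + r * 0.094)
  full <- coef[["c1"]] + coef[["c2"]] * t + coef[["c3"]] * r + coef[["c4"]] * t * r +
    coef[["c5"]] * t^2 + coef[["c6"]] * r^2 + coef[["c7"]] * t^2 * r +
    coef[["c8"]] * t * r^2 + coef[["c9"]] * t^2 * r^2
  lowRh <- !is.na(r) & !is.na(t) & r < 13 & t >= 80 & t <= 112
  full[lowRh] <- full[lowRh] -
    ((13 - r[lowRh]) / 4) * sqrt((17 - abs(t[lowRh] - 95)) / 17)
  highRh <- !is.na(r) & !is.na(t) & r > 85 & t >= 80 & t <= 87
  full[highRh] <- full[highRh] +
    ((r[highRh] - 85) / 10) * ((87 - t[highRh]) / 2)
  out <- ifelse((simple + t) / 2 < 80, simple, full)
  out[is.na(t) | is.na(r)] <- NA_real_
  out
}

#' Apparent temperature in °C
#'
#' Public Celsius interface: converts to °F, applies [heatIndexF()], and
#' converts the result back to °C. The regression's native unit is °F; the
#' round-trip conversion is exact to floating precision.
#'
#' @inheritParams heatIndexF
#' @param tempC dry-bulb temperature, °C.
#' @return apparent temperature, °C.
#' @examples
#' apparentTemperatureC(35, 70)
#' @export
apparentTemperatureC <- function(tempC, rh, coef = heatIndexCoefficients()) {
  fahrenheitToCelsius(heatIndexF(celsiusToFahrenheit(tempC), rh, coef = coef))
}

#' Temperature unit conversions
#' @param x temperature values.
#' @return converted values.
#' @export
celsiusToFahrenheit <- function(x) x * 9 / 5 + 32

#' @rdname celsiusToFahrenheit
#' @export
fahrenheitToCelsius <- function(x) (x - 32) * 5 / 9
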