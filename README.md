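# humidheat

Humid heat-wave hazard indices from daily maximum temperature and daily
minimum relative humidity.

Heat waves whose days are both hot and humid stress the human body far more
than dry ones at the same air temperature, because humidity suppresses
evaporative cooling. `humidheat` is for climate-impact and climate-health
analysts who want to score that combined hazard consistently across station
series, reanalysis grids and model ensembles, and to express it as
exceedance probabilities at prescribed global warming levels.

## What it computes

* **Apparent temperature (heat index)** — the NOAA regression
  `AT = c1 + c2·T + c3·R + c4·T·R + c5·T² + c6·R² + c7·T²·R + c8·T·R² + c9·T²·R²`
  (T in °F, R in %), with all fact-sheet piecewise adjustments, exposed in
  °C (`apparentTemperatureC()`).
* **Heat waves** — runs of ≥ 3 consecutive days with Tmax strictly above the
  calendar-day 90th-percentile threshold (31-day window, reference period
  1981–2010 by default), detected by `detectHeatwaves()`.
* **HWMId** — the yearly maximum over heat waves of the summed daily
  magnitudes `M_d = (T_d − T25) / (T75 − T25)` for `T_d > T25` (else 0),
  normalised by the 25th/75th percentiles of the 30 reference-period annual
  maxima.
* **AHWI** — the same index with AT substituted on days where AT > T; the
  AHWI/HWMId ratio reads directly as a humidity amplification factor, and
  AHWI ≥ HWMId always holds. A heat wave is *humid* if at least one of its
  days has AT > T.
* **WSDI, AT_peak, AT40C/AT55C** — the duration of the year's
  maximum-magnitude event; the maximum AT over the year's heat-wave days;
  and strict binary flags for peaks above 40 °C (US heat-advisory level)
  and 55 °C (heat stroke very likely).
* **ETCCDI-style in-base bootstrap correction** — removes the discontinuity
  between index values inside and outside the threshold reference period
  (`inbaseCorrectedIndices()`, or `annualIndices(..., inbaseCorrection = TRUE)`).
* **Warming-level probabilities** — cosine-weighted global-mean anomalies,
  selection of all model-years within `level ± 0.1` °C of a warming level
  (closed window, pooled across runs), and empirical exceedance
  probabilities per location for definitions such as `"AHWI>60"` or the
  AT40C flag (`selectWarmingYears()`, `hazardProbabilityMaps()`).
* **Synthetic data** — a fully seeded generator of daily Tmax/RHmin series
  and grids (seasonal cycle, AR(1) anomalies, negative T–RH coupling,
  injectable events) and of multi-run GMST trajectories, so every pipeline
  stage is testable without external archives.

## Worked example

```r
library(humidheat)

# 35 C at 70 % relative humidity feels like:
apparentTemperatureC(35, 70)
#> [1] 50.34058

# A 40-year synthetic warm-humid site, thresholds from 1981-2010:
s    <- generateSeries(synthPreset("site40y", seed = 7))
clim <- thresholdClimatology(s, c(1981L, 2010L))
head(annualIndices(s, clim)[, 1:8], 3)
#>   year hwmid  ahwi wsdi atPeak at40c at55c nEvents
#> 1 1976  3.20 23.4     5   59.5     1     1       5
#> 2 1977  1.15 19.4     3   58.2     1     1       2
#> 3 1978  0.00  0.0     4   24.7     0     0       2
```

Reading the 1976 row: the strongest heat wave of that year summed to a
temperature-only magnitude (HWMId) of 3.2 and lasted 5 days (WSDI); with
humidity substituted on days where AT > T the magnitude (AHWI) rises to
23.4 — a ~7× humidity amplification; the hottest apparent temperature
reached during any heat wave was 59.5 °C, so both the 40 °C and 55 °C
danger flags are set.

Event-level detail, the form used to report individual heat waves:

```r
detectHeatwaves(s, clim, years = 2003L)[, c("startMonth", "duration",
                                            "magnitudeSum", "atPeak", "humid")]
#>   startMonth duration magnitudeSum atPeak humid
#> 1          5        3        0.000   35.6  TRUE
#> 2          5        3        0.000   38.4  TRUE
#> 3         12        6        0.000   21.0 FALSE
#> 4         12        3        0.000   18.7 FALSE
```

Warming-level hazard maps from a synthetic 9-run ensemble:

```r
gmst <- generateGmstRuns(9, 1861:2100, scenario = c("stabilize", "ramp"),
                         rampTo = 5, noiseSd = 0.1, seed = 2)
ws   <- selectWarmingYears(gmst, level = 2)   # all model-years at 2 +/- 0.1 C
ws
#> WarmingLevelSample: 2.00 °C ± 0.10 relative to 1861-1880, 75 member-years
```

A command-line interface wraps the same functions
(`exec/humidheat at --temp-c 35 --rh 70`, plus `synth`, `indices` and
`probability` subcommands).

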