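---
title: "Quantifying humid heat-wave hazard: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying humid heat-wave hazard: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humidheat)
```

# The problem

A heat wave whose days are merely hot ranks differently from one whose days
are hot *and* humid: high relative humidity suppresses evaporative cooling,
so the physiological load at a given air temperature rises sharply with
moisture. `humidheat` quantifies this from the two daily fields that climate
models and reanalyses commonly provide — daily maximum near-surface
temperature (Tmax, °C) and daily minimum relative humidity (RHmin, %). The
minimum of the diurnal humidity cycle is used because, to first
approximation, it co-occurs with the daily temperature maximum; where
simultaneous humidity is available the indices would if anything be larger,
so results here are conservative.

# Apparent temperature

The apparent temperature (heat index) is the NOAA regression
$$AT = c_1 + c_2 T + c_3 R + c_4 TR + c_5 T^2 + c_6 R^2 + c_7 T^2R
  + c_8 TR^2 + c_9 T^2R^2,$$
with $T$ in °F and $R$ in %, wrapped in the NOAA fact-sheet's piecewise
rules: a simple linear formula applies when its average with $T$ stays below
80 °F; a low-humidity correction is subtracted for $R < 13\,\%$,
$80 \le T \le 112$ °F; a high-humidity correction is added for
$R > 85\,\%$, $80 \le T \le 87$ °F. The implementation computes in the
regression's native °F and exposes °C at every public boundary
(`apparentTemperatureC()`).

Two numerical points deserve note. First, a transcription of the $c_9$
coefficient as $-0.199 \times 10^{-6}$ circulates in the literature; with it
the regression returns about 177 °F at (90 °F, 70 %) where the published
chart has 105 °F. The package defaults to the NOAA value
$-1.99 \times 10^{-6}$ and leaves $c_9$ user-configurable so the variant can
be reproduced deliberately. Second, no clamping is applied above the chart's
validity range: hazard analysis is exactly where extreme arguments occur,
so values are reported as computed, with a warning once inputs exceed
130 °F.

# Heat waves and their magnitude

A heat wave is at least three consecutive days with Tmax strictly above the
calendar-day threshold: the 90th percentile of reference-period (default
1981–2010) daily values pooled over a centred 31-day window. "Exceeding"
is read as strict `>`; the comparator is configurable. Pooling is circular
over the calendar (early January draws on late December), and February 29
is its own calendar key whose window simply collects fewer values in
non-leap years. All percentiles in the package — daily thresholds, annual-max
percentiles, bootstrap surrogates — use the same estimator, the empirical
distribution with linear interpolation (R's `type = 7`), which is the
convention in climate-index software. A calendar day whose pooled sample
retains less than 80 % of its nominal size yields a missing threshold; the
cut-off is a completeness guard of our choosing, not a sensitivity point in
any of the shipped analyses.

Each heat-wave day contributes the dimensionless magnitude
$$M_d(T_d) = \begin{cases}
  \dfrac{T_d - T_{25}}{T_{75} - T_{25}} & T_d > T_{25},\\[4pt]
  0 & T_d \le T_{25},
\end{cases}$$
where $T_{25}$ and $T_{75}$ are the 25th/75th percentiles of the 30
reference-period annual maxima. Magnitudes sum over an event's days; the
annual HWMId is the maximum sum across the year's events. The apparent
index (AHWI) is computed identically except that the magnitude argument on
a day is $AT_d$ whenever $AT_d > T_d$. Degenerate normalisation
($T_{25} = T_{75}$, e.g. constant series) returns 0 at or below $T_{25}$
and missing-with-warning above, rather than an infinity.

Design choices that the definitions leave open, and how we resolved them:

* **AHWI normalisation.** AHWI reuses the temperature-based
  $(T_{25}, T_{75})$ and the temperature-based event days, substituting AT
  only as the magnitude argument. This makes the AHWI/HWMId ratio directly
  readable as a humidity amplification factor and guarantees
  AHWI ≥ HWMId. An alternative mode that normalises by percentiles of
  annual maxima of $\max(T, AT)$ is available
  (`apparentNormalization = TRUE` plus
  `ahwiNormalization = "apparent"`), but is not the default because it
  breaks that ordering guarantee and the two indices stop being
  comparable on one scale.
* **Year attribution.** An event belongs to the year of its first day and
  is never split at December 31; "consecutive days" semantics take
  precedence over calendar bookkeeping.
* **WSDI.** Reported annually as the duration of the year's
  maximum-magnitude event; per-event durations remain available on the
  event table, which is the per-heat-wave form used when reporting single
  events.
* **AT peak.** Taken over all heat-wave days of the year, not only humid
  ones. The danger flags are strict: AT40C requires `atPeak > 40` °C
  (≈105 °F, the US heat-advisory level), AT55C requires `atPeak > 55` °C
  (≈130 °F, heat stroke very likely); a peak of exactly 40 °C does not
  raise the flag. Missing humidity disables the AT family rather than
  silently degrading it: `ahwi()` raises an instructive error.

# In-base bootstrap correction

Years inside the reference period help set their own thresholds, which
systematically depresses threshold-relative indices there relative to
out-of-base years. The package implements the standard ETCCDI-style
resampling remedy: for each in-base year $y$, remove $y$, and for each of
the 29 remaining years $z$ build a 30-year surrogate base with $z$ counted
twice; the corrected value for $y$ is the mean of the 29 index evaluations.
Daily thresholds *and* the $(T_{25}, T_{75})$ pair are recomputed jointly
per surrogate, so the correction covers event detection, normalisation and
the AT substitution consistently. The surrogate threshold evaluation is
implemented in C++ (the inner loop is 29 quantile passes over ~930-value
pools for each of 366 calendar days); the C++ quantile reproduces R's
`quantile(type = 7)` arithmetic exactly, which the test suite verifies.

The continuity experiment in the test suite uses 120 stationary synthetic
60-year series (30-year base). Because annual HWMId is a yearly maximum —
and therefore heavy-tailed — the raw contrast between 30-year in-base and
out-of-base means is dominated by a few extreme events and converges slowly.
The experiment therefore tests two things separately: the corrected in-base
mean must lie within two Monte-Carlo standard errors of the out-of-base
mean, and the in-base *discontinuity* — uncorrected minus corrected values
on the same years and weather draws, a paired statistic with roughly an
order of magnitude smaller error — must be significantly negative (the
classic in-base depression). Under white-noise anomalies the depression is
undetectable at these scales for HWMId (three-day exceedance runs are
vanishingly rare, so there is little heat-wave signal for the bias to act
on); autocorrelated anomalies, the realistic and default regime, produce
both the heat waves and the measurable bias.

# Warming levels and empirical probability

Global-mean series are cosine-of-latitude weighted means of annual-mean
fields, centred on a 1861–1880 baseline; missing cells renormalise the
weights with a coverage warning below 95 %. A warming-level sample pools,
across runs and scenarios with equal weight, every (run, year) whose
anomaly lies in the *closed* window `level ± 0.1` °C — the closed interval
matches the "between 1.4° and 1.6°" reading of a 1.5° level. Membership
uses annual anomalies; decadal medians are provided only as a display
summary (`decadalMedianGmst()`).

The empirical probability of a hazard (for example `AHWI > 60`, or the
AT40C flag) at a location is the count of member-years with the event over
the count of usable member-years; its reciprocal is the average return
period. Event definitions are parsed strings, so the comparator is explicit
per definition: the named flags AT40C/AT55C carry their strict `>`
definition, while `"AT_peak>=40"` style expressions choose their own.
Nested definitions inherit their ordering: AHWI-based exceedance
probabilities dominate HWMId-based ones pointwise, and AT40C dominates
AT55C.

# The synthetic generator

`synthConfig()`/`generateSeries()` emulate the statistical features the
indices rely on, not the physics of any model: a sinusoidal seasonal Tmax
cycle (northern mid-summer peak), AR(1) daily anomalies, humidity generated
conditionally on the temperature anomaly, an optional linear trend, and
injectable multi-day events. Defaults describe a warm humid site: annual
mean 22 °C, seasonal half-range 10 °C, lag-1 autocorrelation 0.7
(so multi-day exceedance runs occur at realistic rates), stationary anomaly
SD 3 °C, RHmin mean 60 % with SD 8 % and a −2 %/°C coupling — the negative
temperature–humidity correlation typical of daily data. `dailySdC` is
deliberately the *stationary* anomaly SD (innovations are scaled by
$\sqrt{1-\phi^2}$), so detection margins can be stated in units of it.
All randomness flows from a single seed; grid cells and GMST runs draw from
substreams derived deterministically from (seed, index), and the generator
draws all temperature innovations before all humidity innovations so that
two configurations differing only in an event's humidity boost share the
identical temperature realisation (common random numbers).

The event-recovery experiment in the test suite places injected events on
the spring ramp of a strongly seasonal, low-noise configuration
(`seasonalAmpC = 15`, `dailySdC = 1`). That regime is what makes *exact*
start/duration recovery a well-posed demand: within the 31-day pooling
window the seasonal slope lifts the 90th-percentile threshold by about
3 SD above the central day's mean, so background exceedances next to the
injected event are rare. Under the generator's default noise level the
threshold margin is by construction about the 90th percentile of the
anomaly distribution, ~10 % of neighbouring days exceed it, and no detector
can pin event boundaries exactly — a limitation of the *definition*, not of
the implementation. Amplitudes are set per replicate to the realised
threshold margin plus 3.5 stationary SD, satisfying the margin-plus-3-SD
condition under which ≥99 % exact recovery is asserted over 1,000
replicates.

What passing these tests shows — and does not. The generator produces
stationary (or linearly trending) Gaussian anomalies with a fixed seasonal
cycle. Real daily temperature has skewed tails, regime-dependent
persistence, and humidity whose coupling to temperature varies by season
and circulation; none of that is emulated. Passing the suite demonstrates
the estimators' correctness and internal consistency, not that any real
region exhibits the simulated hazard rates.

# Numerical and interface choices

* Problem sizes in the shipped experiments: 120 × 60-year series for
  bootstrap continuity, 1,000 injected-event replicates, an 8 × 8 cell,
  150-year grid for the map-ordering checks. These were chosen as the
  smallest sizes at which the statistical assertions have comfortable
  power on a single core.
* Grid and series I/O is plain CSV with `# key: value` metadata headers
  (calendar, units, coordinates, reference period); Kelvin and fractional
  humidity convert at the read boundary. Calendars `standard`, `noleap`
  and `360_day` are honoured end-to-end: threshold vectors have 366, 365
  and 360 calendar-day keys respectively.
* Bilinear regridding normalises longitudes to \[0, 360), wraps across the
  dateline, and marks target points outside the source hull (nearest-edge
  values) in an `"extrapolated"` attribute instead of silently
  extrapolating.
* Ties and degenerate inputs: threshold comparisons are strict, so a day
  exactly at its threshold splits a spell; constant reference series give
  degenerate normalisation handled as above; an empty warming-level window
  is an error that reports the nearest available anomalies rather than an
  empty sample.

# Known limitations

* Wet-bulb-based thresholds (e.g. the 35 °C survivability line) are out of
  scope; the package deliberately implements only the AT family.
* The bootstrap correction returns fractional event counts and durations
  (means over 29 surrogates); consumers needing integers should round
  explicitly.
* `empiricalProbability()` treats member-years as exchangeable; no model
  weighting or autocorrelation correction is applied to the binomial
  counts.
* The generator's humidity is Gaussian and clipped to \[0, 100\]; at very
  humid configurations the clipping induces mild distortion near the
  boundaries.
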