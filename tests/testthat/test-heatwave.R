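test_that("daily magnitude follows the piecewise normalisation exactly", {
  expect_equal(dailyMagnitude(30, 30, 34), 0)    # at t25
  expect_equal(dailyMagnitude(34, 30, 34), 1)    # at t75
  expect_equal(dailyMagnitude(38, 30, 34), 2)    # t25 + 2 * (t75 - t25)
  expect_equal(dailyMagnitude(25, 30, 34), 0)    # below t25
  expect_error(dailyMagnitude(30, 35, 34), "t25")
  # degenerate normalisation
  expect_equal(dailyMagnitude(20, 25, 25), 0)
  expect_warning(m <- dailyMagnitude(30, 25, 25), "degenerate")
  expect_true(is.na(m))
})

test_that("runs shorter than three days are not events and ties split spells", {
  clim <- flatClimatology(threshold = 25, t25 = 28, t75 = 32)
  # two consecutive exceedance days only -> nothing
  s2 <- toyYearSeries(c(26, 26), 7, 10)
  expect_equal(nrow(detectHeatwaves(s2, clim)), 0)
  # five consecutive exceedance days -> one event of duration 5
  s5 <- toyYearSeries(rep(26, 5), 7, 10)
  ev <- detectHeatwaves(s5, clim)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 5)
  expect_equal(wsdi(ev), 5)
  # tmax equal to the threshold in the middle -> strict > splits the spell
  sTie <- toyYearSeries(c(26, 26, 25, 26, 26), 7, 10)
  expect_equal(nrow(detectHeatwaves(sTie, clim)), 0)
  # non-strict mode keeps it together
  expect_equal(nrow(detectHeatwaves(sTie, clim, strict = FALSE)), 1)
})

test_that("missing days terminate runs and missing years warn upstream", {
  clim <- flatClimatology(25, 28, 32)
  s <- toyYearSeries(c(26, 26, NA, 26, 26), 7, 10)
  expect_equal(nrow(detectHeatwaves(s, clim)), 0)
  sLong <- toyYearSeries(c(26, 26, 26, NA, 26, 26, 26), 7, 10)
  ev <- detectHeatwaves(sLong, clim)
  expect_equal(ev$duration, c(3L, 3L))
})

test_that("hwmid, ahwi and wsdi reduce events as specified", {
  clim <- flatClimatology(25, t25 = 30, t75 = 34)
  # 3 days at t75 -> each magnitude 1 -> HWMId 3
  s <- toyYearSeries(rep(34, 3), 7, 10)
  ev <- detectHeatwaves(s, clim)
  expect_equal(hwmid(ev), 3)
  # no events -> all zeros
  ev0 <- detectHeatwaves(toyYearSeries(20, 7, 10), clim)
  expect_equal(hwmid(ev0), 0)
  expect_equal(wsdi(ev0), 0L)
  expect_equal(ahwi(ev0), 0)
  # two events, durations {4, 7} with magnitude sums {5, 3}: the maximum
  # magnitude wins and WSDI is that event's duration
  sTwo <- toyYearSeries(c(rep(35, 4), 20, rep(30 + 4 * 3 / 7, 7)), 7, 1)
  evTwo <- detectHeatwaves(sTwo, clim)
  expect_equal(nrow(evTwo), 2)
  expect_equal(evTwo$magnitudeSum, c(5, 3))
  expect_equal(hwmid(evTwo), 5)
  expect_equal(wsdi(evTwo), 4L)
})

test_that("AHWI substitutes AT only where it exceeds T and dominates HWMId", {
  clim <- flatClimatology(25, t25 = 30, t75 = 34)
  # choose humidity so AT doubles the magnitude: need AT = 38 when T = 34
  rhNeeded <- uniroot(function(r) apparentTemperatureC(34, r) - 38,
                      c(0, 100))$root
  s <- toyYearSeries(rep(34, 3), 7, 10, rhmin = rep(rhNeeded, 3))
  ev <- detectHeatwaves(s, clim)
  expect_equal(ahwi(ev), 6, tolerance = 1e-6)   # twice the HWMId of 3
  expect_equal(hwmid(ev), 3)
  expect_true(ev$humid)
  # dry case: AT below T leaves AHWI equal to HWMId
  sDry <- toyYearSeries(rep(34, 3), 7, 10, rhmin = rep(0, 3))
  evDry <- detectHeatwaves(sDry, clim)
  expect_equal(ahwi(evDry), hwmid(evDry))
  expect_false(evDry$humid)
  # rhmin absent entirely -> ahwi refuses, pointing at hwmid
  sNoRh <- toyYearSeries(rep(34, 3), 7, 10)
  expect_error(ahwi(detectHeatwaves(sNoRh, clim)), "hwmid")
})

test_that("AT peak and danger flags use strict comparisons", {
  ev <- data.frame(atPeak = c(38, 41, 39))
  pk <- atPeakAndFlags(ev)
  expect_equal(pk$atPeak, 41)
  expect_equal(pk$at40c, 1L)
  expect_equal(pk$at55c, 0L)
  # exactly 40 C does not raise the flag
  pk40 <- atPeakAndFlags(data.frame(atPeak = 40))
  expect_equal(pk40$at40c, 0L)
  # no events
  pk0 <- atPeakAndFlags(data.frame(atPeak = numeric()))
  expect_true(is.na(pk0$atPeak))
  expect_equal(c(pk0$at40c, pk0$at55c), c(0L, 0L))
})

test_that("events crossing Dec 31 stay whole and belong to the start year", {
  cal1 <- humidheat:::.yearCalendar(2001, "standard")
  cal2 <- humidheat:::.yearCalendar(2002, "standard")
  tmax <- rep(10, nrow(cal1) + nrow(cal2))
  tmax[(nrow(cal1) - 1):(nrow(cal1) + 2)] <- 26   # Dec 30 - Jan 2
  s <- dailyClimateSeries(tmax = tmax,
                          year = c(cal1$year, cal2$year),
                          month = c(cal1$month, cal2$month),
                          day = c(cal1$day, cal2$day))
  clim <- flatClimatology(25, 28, 32)
  ev <- detectHeatwaves(s, clim)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$year, 2001L)
  expect_equal(ev$duration, 4L)
  rec <- annualIndices(s, clim)
  expect_equal(rec$nEvents, c(1L, 0L))
  expect_equal(rec$wsdi, c(4L, 0L))
})

test_that("annual records satisfy the structural invariants on synthetic data", {
  s <- generateSeries(synthConfig(years = 1981:2012, seed = 21))
  clim <- thresholdClimatology(s, c(1981L, 2010L))
  rec <- annualIndices(s, clim)
  expect_true(all(rec$hwmid >= 0))
  expect_true(all(rec$ahwi >= rec$hwmid))
  expect_true(all(rec$at40c >= rec$at55c))
  expect_true(all((rec$wsdi == 0) == (rec$nEvents == 0)))
  ev <- detectHeatwaves(s, clim)
  expect_true(all(ev$apparentMagnitudeSum >= ev$magnitudeSum))
  expect_gte(sum(ev$duration), 3 * nrow(ev))
  expect_equal(ev$humid,
               vapply(seq_len(nrow(ev)),
                      function(i) any(ev$dailyAt[[i]] > ev$dailyTmax[[i]]),
                      logical(1)))
})

test_that("the whole pipeline is equivariant under a constant temperature shift", {
  cfg <- synthConfig(years = 1996:2010, rhMean = 0, rhSd = 0,
                     tRhCoupling = 0, seed = 22)
  s <- generateSeries(cfg)
  sShift <- s
  sShift@tmax <- s@tmax + 2
  ref <- c(1996L, 2010L)
  r1 <- annualIndices(s, thresholdClimatology(s, ref))
  r2 <- annualIndices(sShift, thresholdClimatology(sShift, ref))
  expect_equal(r1$hwmid, r2$hwmid)
  expect_equal(r1$wsdi, r2$wsdi)
  expect_equal(r1$nEvents, r2$nEvents)
})
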