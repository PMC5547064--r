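test_that("generation is bit-identical under a repeated seed", {
  cfg <- synthConfig(years = 1991:2000, seed = 77)
  s1 <- generateSeries(cfg)
  s2 <- generateSeries(cfg)
  expect_identical(s1@tmax, s2@tmax)
  expect_identical(s1@rhmin, s2@rhmin)
  s3 <- generateSeries(synthConfig(years = 1991:2000, seed = 78))
  expect_false(identical(s1@tmax, s3@tmax))
  g1 <- generateGmstRuns(2, 1991:2010, seed = 3)
  g2 <- generateGmstRuns(2, 1991:2010, seed = 3)
  expect_identical(g1, g2)
})

test_that("zero noise and no events reduce to the deterministic seasonal cycle", {
  cfg <- synthConfig(years = 2001:2002, dailySdC = 0, rhSd = 0, seed = 1)
  s <- generateSeries(cfg)
  doy <- sequence(c(365L, 365L))
  expect_equal(s@tmax, seasonalCycle(cfg, doy), tolerance = 1e-12)
  # a trend tilts the second year upward by trendPerDecade / 10
  cfgT <- synthConfig(years = 2001:2002, dailySdC = 0, rhSd = 0,
                      trendPerDecade = 1, seed = 1)
  sT <- generateSeries(cfgT)
  expect_equal(sT@tmax[366:730] - s@tmax[366:730], rep(0.1, 365))
})

test_that("temperature anomalies and humidity are negatively coupled", {
  s <- generateSeries(synthConfig(years = 1981:2010, seed = 55))
  # remove the seasonal cycle by monthly means before correlating
  anom <- s@tmax - ave(s@tmax, s@month)
  expect_lt(cor(anom, s@rhmin), -0.3)
  expect_true(all(s@rhmin >= 0 & s@rhmin <= 100))
})

test_that("daily anomalies carry the configured autocorrelation", {
  cfg <- synthConfig(years = 1981:2010, seed = 56)
  s <- generateSeries(cfg)
  anom <- s@tmax - ave(s@tmax, s@month)
  expect_equal(cor(anom[-1], anom[-length(anom)]), cfg@ar1, tolerance = 0.05)
  expect_equal(sd(anom), cfg@dailySdC, tolerance = 0.15)
})

test_that("an injected event is detected at its exact start and duration", {
  ev <- data.frame(year = 2011L, startDay = 120L, duration = 5L,
                   amplitude = 18, rhBoost = 0)
  cfg <- synthConfig(years = 1981:2011, events = ev, seed = 57)
  s <- generateSeries(cfg)
  clim <- thresholdClimatology(s, c(1981L, 2010L))
  found <- detectHeatwaves(s, clim, years = 2011L)
  hit <- found[found$duration == 5L, ]
  expect_equal(nrow(hit), 1)
  cal <- humidheat:::.yearCalendar(2011, "standard")
  expect_equal(hit$startMonth, cal$month[120])
  expect_equal(hit$startDay, cal$day[120])
})

test_that("a humidity boost raises AHWI but leaves HWMId unchanged", {
  ev0 <- data.frame(year = 2011L, startDay = 200L, duration = 4L,
                    amplitude = 15, rhBoost = 0)
  ev1 <- transform(ev0, rhBoost = 30)
  base <- synthConfig(years = 1981:2011, events = ev0, seed = 58)
  boost <- synthConfig(years = 1981:2011, events = ev1, seed = 58)
  s0 <- generateSeries(base)
  s1 <- generateSeries(boost)
  expect_identical(s0@tmax, s1@tmax)   # common random numbers
  ref <- c(1981L, 2010L)
  r0 <- annualIndices(s0, thresholdClimatology(s0, ref), years = 2011L)
  r1 <- annualIndices(s1, thresholdClimatology(s1, ref), years = 2011L)
  expect_equal(r0$hwmid, r1$hwmid)
  expect_gt(r1$ahwi, r0$ahwi)
})

test_that("GMST scenarios follow their closed forms", {
  g <- generateGmstRuns(1, 1901:2100, scenario = "ramp", rampTo = 4,
                        noiseSd = 0, seed = 1)
  expect_equal(g$anomaly, 4 * (0:199) / 199)
  gs <- generateGmstRuns(1, 1901:2100, scenario = "stabilize", capAt = 1.8,
                         noiseSd = 0, seed = 1)
  expect_lt(max(gs$anomaly), 1.8 + 1e-9)
  expect_gt(max(gs$anomaly), 1.7)
})

test_that("grid cells have distinct substreams and a latitude gradient", {
  cfg <- synthConfig(years = 2001:2005, lats = c(30, 40), lons = c(0, 10),
                     seed = 60)
  g <- generateGrid(cfg)
  expect_false(identical(gridCell(g, 1, 1)@tmax, gridCell(g, 2, 1)@tmax))
  expect_gt(mean(gridCell(g, 1, 1)@tmax), mean(gridCell(g, 2, 1)@tmax))
  g2 <- generateGrid(cfg)
  expect_identical(gridCell(g2, 2, 2)@tmax, gridCell(g, 2, 2)@tmax)
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(years = c(2001, 2003)), "contiguous")
  expect_error(synthConfig(ar1 = 1), "ar1")
  expect_error(synthConfig(rhMean = 130), "rhMean")
})
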