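makeConstantSeries <- function(years, value = 20, calendar = "standard") {
  cal <- do.call(rbind, lapply(years, humidheat:::.yearCalendar, calendar = calendar))
  dailyClimateSeries(tmax = rep(value, nrow(cal)), year = cal$year,
                     month = cal$month, day = cal$day, calendar = calendar)
}

test_that("constant series gives constant thresholds and degenerate percentiles", {
  s <- makeConstantSeries(2001:2004)
  thr <- dailyThreshold(s, c(2001L, 2004L))
  expect_length(thr, 366)
  expect_true(all(thr == 20))
  q <- annualMaxPercentiles(s, c(2001L, 2004L))
  expect_equal(unname(q), c(20, 20))
})

test_that("single-year 3-day window reproduces the hand-computed quantile", {
  s <- makeConstantSeries(2001:2001, value = 15)
  # place 10, 20, 30 on July 14-16; threshold for July 15 pools exactly those
  i <- which(s@month == 7 & s@day %in% 14:16)
  s@tmax[i] <- c(10, 20, 30)
  thr <- dailyThreshold(s, c(2001L, 2001L), windowDays = 3L)
  # type-7 90th percentile of {10, 20, 30} = 28
  expect_equal(unname(thr["07-15"]), 28)
})

test_that("thresholds cover all 366 calendar days including Feb 29", {
  s <- makeConstantSeries(1999:2002)  # one leap year in the reference
  thr <- dailyThreshold(s, c(1999L, 2002L))
  expect_false(anyNA(thr))
  expect_true("02-29" %in% names(thr))
})

test_that("a 360-day calendar yields 360 thresholds and no Feb-29 key", {
  s <- makeConstantSeries(2001:2003, calendar = "360_day")
  thr <- dailyThreshold(s, c(2001L, 2003L))
  expect_length(thr, 360)
  expect_true("02-30" %in% names(thr))   # every month has 30 days
  expect_false("01-31" %in% names(thr))  # and none has a 31st
})

test_that("annual-max percentiles match the type-7 hand computation", {
  s <- makeConstantSeries(2001:2004, value = 0)
  for (y in 2001:2004) {
    s@tmax[which(s@year == y)[180]] <- c(30, 32, 34, 36)[y - 2000]
  }
  q <- annualMaxPercentiles(s, c(2001L, 2004L))
  expect_equal(unname(q), c(31.5, 34.5))
  expect_gt(q["t75"], q["t25"])
})

test_that("fully missing reference years are excluded with a warning", {
  s <- makeConstantSeries(2001:2004, value = 25)
  s@tmax[s@year == 2003] <- NA_real_
  expect_warning(q <- annualMaxPercentiles(s, c(2001L, 2004L)), "missing")
  expect_equal(unname(q), c(25, 25))
  s2 <- makeConstantSeries(2001:2002)
  s2@tmax[s2@year == 2002] <- NA_real_
  expect_error(suppressWarnings(annualMaxPercentiles(s2, c(2001L, 2002L))),
               "fewer than 2")
})

test_that("reference period outside the series errors; empty pools warn", {
  s <- makeConstantSeries(2001:2004)
  expect_error(dailyThreshold(s, c(1990L, 2010L)), "reference period")
  s@tmax[s@month %in% 5:9] <- NA_real_   # knock out the whole warm season
  expect_warning(thr <- dailyThreshold(s, c(2001L, 2004L)), "insufficient")
  expect_true(anyNA(thr))
})

test_that("thresholds and percentiles are equivariant under a constant shift", {
  cfg <- synthConfig(years = 2001:2010, seed = 11)
  s <- generateSeries(cfg)
  sShift <- s
  sShift@tmax <- s@tmax + 3.5
  ref <- c(2001L, 2010L)
  expect_equal(dailyThreshold(sShift, ref), dailyThreshold(s, ref) + 3.5)
  expect_equal(annualMaxPercentiles(sShift, ref),
               annualMaxPercentiles(s, ref) + 3.5)
})

test_that("daily thresholds are non-decreasing in the quantile level", {
  s <- generateSeries(synthConfig(years = 2001:2005, seed = 12))
  ref <- c(2001L, 2005L)
  t80 <- dailyThreshold(s, ref, quantileProb = 0.8)
  t90 <- dailyThreshold(s, ref, quantileProb = 0.9)
  t95 <- dailyThreshold(s, ref, quantileProb = 0.95)
  expect_true(all(t90 >= t80) && all(t95 >= t90))
})

test_that("windowed pooling agrees with a direct R quantile computation", {
  s <- generateSeries(synthConfig(years = 2001:2003, seed = 13))
  thr <- dailyThreshold(s, c(2001L, 2003L))
  keys <- calendarKeys("standard")
  for (kq in c(30, 180, 366)) {   # late Jan, late June, Dec 31 (wraps)
    K <- nrow(keys)
    wanted <- ((kq - 1 + seq(-15, 15)) %% K) + 1
    pool <- s@tmax[humidheat:::.keyIndex(s@month, s@day, "standard") %in% wanted]
    expect_equal(unname(thr[kq]),
                 unname(quantile(pool, 0.9, type = 7, names = FALSE)))
  }
})
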