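test_that("global means are cosine-weighted and baseline-centred", {
  years <- 1861:1900
  # spatially uniform field: weights cancel, anomaly is the centred series
  vals <- seq(10, 13.9, by = 0.1)
  arr <- array(rep(vals, 4), dim = c(40, 2, 2),
               dimnames = list(years, NULL, NULL))
  gm <- globalMeanAnomaly(arr, lats = c(10, 60), baselinePeriod = c(1861L, 1880L))
  expect_equal(gm$anomaly, vals - mean(vals[1:20]))
  base <- gm$year >= 1861 & gm$year <= 1880
  expect_equal(mean(gm$anomaly[base]), 0)
})

test_that("polar-only fields weigh less than an unweighted mean", {
  # two latitude bands, zero baseline year, signal only in the 70° band
  arr <- array(0, dim = c(2, 2, 1), dimnames = list(c("2000", "2001"), NULL, NULL))
  arr[2, 2, 1] <- 10
  lats <- c(0, 70)
  gm <- globalMeanAnomaly(arr, lats, baselinePeriod = c(2000L, 2000L))
  # closed form: 10 * cos(70°) / (cos(0°) + cos(70°)) < unweighted mean of 5
  w <- cos(70 * pi / 180)
  expect_equal(gm$anomaly[2], 10 * w / (1 + w))
  expect_lt(gm$anomaly[2], mean(c(0, 10)))
  # weights renormalise over available cells, with a coverage warning
  arr2 <- array(c(5, 5, 5, NA), dim = c(2, 2, 1),
                dimnames = list(c("2000", "2001"), NULL, NULL))
  expect_warning(gm2 <- globalMeanAnomaly(arr2, lats, c(2000L, 2000L)), "coverage")
  expect_equal(gm2$anomaly, c(0, 0))
})

test_that("warming-level membership uses the closed interval", {
  gmst <- data.frame(run = "r1", year = 2001:2004,
                     anomaly = c(1.39, 1.40, 1.55, 1.61))
  ws <- selectWarmingYears(gmst, 1.5)
  expect_equal(sort(sampleMembers(ws)$year), c(2002L, 2003L))
  expect_equal(sampleSize(ws), 2L)
})

test_that("a monotone ramp yields a contiguous block; empty windows error", {
  g <- generateGmstRuns(1, years = 1901:2100, scenario = "ramp",
                        rampTo = 4, noiseSd = 0, seed = 1)
  ws <- selectWarmingYears(g, 2.0)
  yrs <- sort(sampleMembers(ws)$year)
  expect_equal(yrs, seq(min(yrs), max(yrs)))
  expect_equal(length(yrs), 10L)  # 200 years * (0.2 / 4)
  capped <- generateGmstRuns(1, years = 1901:2100, scenario = "stabilize",
                             capAt = 1.8, noiseSd = 0, seed = 1)
  expect_error(selectWarmingYears(capped, 4.0), "nearest")
})

test_that("empirical probabilities are event counts over usable trials", {
  members <- data.frame(run = "r1", year = 1:115, anomaly = 1.5)
  ws <- new("WarmingLevelSample", level = 1.5, halfwidth = 0.1,
            members = members, baselinePeriod = c(1861L, 1880L))
  bf <- data.frame(run = "r1", year = 1:115, location = "A",
                   event = c(rep(1, 3), rep(0, 112)))
  p <- empiricalProbability(bf, ws)
  expect_equal(p$probability, 3 / 115)
  expect_equal(p$nTrials, 115L)
  # all / none / missing
  bf$event <- 1
  expect_equal(empiricalProbability(bf, ws)$probability, 1)
  bf$event <- 0
  expect_equal(empiricalProbability(bf, ws)$probability, 0)
  bf$event <- NA
  expect_true(is.na(empiricalProbability(bf, ws)$probability))
})

test_that("hazard maps apply nested definitions consistently", {
  members <- data.frame(run = "r1", year = 2001:2010, anomaly = 2)
  ws <- new("WarmingLevelSample", level = 2, halfwidth = 0.1,
            members = members, baselinePeriod = c(1861L, 1880L))
  idx <- expand.grid(run = "r1", year = 2001:2010,
                     location = c("A", "B"), stringsAsFactors = FALSE)
  set.seed(41)
  idx$hwmid <- runif(nrow(idx), 0, 80)
  idx$ahwi <- idx$hwmid + runif(nrow(idx), 0, 30)
  idx$atPeak <- runif(nrow(idx), 30, 60)
  maps <- hazardProbabilityMaps(idx, ws,
                                definitions = c("HWMId>60", "AHWI>60",
                                                "AT40C", "AT55C"))
  expect_true(all(maps[["AHWI>60"]]$probability >=
                    maps[["HWMId>60"]]$probability))
  expect_true(all(maps[["AT40C"]]$probability >=
                    maps[["AT55C"]]$probability))
  for (m in maps) expect_true(all(m$probability >= 0 & m$probability <= 1))
  # explicit comparator expressions and unknown names
  m2 <- hazardProbabilityMaps(idx, ws, definitions = "AT_peak>=40")
  expect_gte(m2[[1]]$probability[1], maps[["AT40C"]]$probability[1])
  expect_error(hazardProbabilityMaps(idx, ws, definitions = "XWMID>60"),
               "unknown index")
})

test_that("membership is order-independent", {
  gmst <- data.frame(run = rep(c("a", "b"), each = 50),
                     year = rep(2001:2050, 2),
                     anomaly = seq(0.5, 2.5, length.out = 100))
  w1 <- selectWarmingYears(gmst, 1.5)
  w2 <- selectWarmingYears(gmst[sample(nrow(gmst)), ], 1.5)
  m1 <- sampleMembers(w1); m1 <- m1[order(m1$run, m1$year), ]
  m2 <- sampleMembers(w2); m2 <- m2[order(m2$run, m2$year), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("decadal medians summarise trajectories", {
  g <- generateGmstRuns(3, years = 1981:2020, scenario = "ramp",
                        rampTo = 2, noiseSd = 0, seed = 5)
  dm <- decadalMedianGmst(g)
  expect_equal(dm$decade, c(1980, 1990, 2000, 2010, 2020))
  expect_true(all(diff(dm$anomaly) > 0))
})
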