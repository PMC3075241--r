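exp <- experimentConfig()

# timeline of one 60 s bout at 5 Hz starting at `startS`, moving `total` mm
# in equal x-steps, optionally labeled
syntheticBoutFrames <- function(startS, total = 0, boutKey = "b1",
                                label = "walking", n = 300L, rateHz = 5) {
  t <- startS + (seq_len(n) - 1) / rateHz
  data.frame(t = t, x = 10 + seq(0, total, length.out = n), y = 75,
             z = 0, label = label, boutKey = boutKey)
}

test_that("bout distance sums displacements and bounds net displacement", {
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))
  b <- bout("f", "c", 0, 1, 3,
            data.frame(t = 0:2, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       label = NA_character_))
  expect_equal(boutDistance(b), 7)
  expect_equal(boutDistance(makeStationaryBout(10)), 0)
  for (seed in 1:10) {
    rb <- randomTestBout(40, seed = seed)
    p <- framePositions(rb)
    expect_gte(boutDistance(rb), sqrt(sum((p[40, ] - p[1, ])^2)))
  }
})

test_that("hourly cells scale recorded activity to full-hour estimates", {
  # one 60 s bout of 10 mm in one hour -> 600 mm estimated for the hour
  tl <- syntheticBoutFrames(3600 * 10, total = 10)
  m <- hourlyActivity(tl, exp)
  expect_equal(dim(m), c(1L, 24L))
  expect_equal(unname(m[1, "h10"]), 600)
  expect_true(all(is.na(m[1, -11])))

  # two 5 mm bouts in the same hour -> 10 mm over 120 s, scaled x30
  tl2 <- rbind(syntheticBoutFrames(3600 * 10, 5, "b1"),
               syntheticBoutFrames(3600 * 10 + 120, 5, "b2"))
  m2 <- hourlyActivity(tl2, exp)
  expect_equal(unname(m2[1, "h10"]), 300)

  # unscaled cells add up to the raw distance exactly
  m3 <- hourlyActivity(tl2, exp, estimateFullHour = FALSE)
  expect_equal(sum(m3, na.rm = TRUE), 10)

  expect_error(hourlyActivity(tl[c(1, 1), ], exp), "overlapping")
})

test_that("behavior-count cells follow the same scaling", {
  tl <- syntheticBoutFrames(3600 * 5, total = 10, label = "walking")
  tl$label[1:30] <- "resting"
  m <- hourlyActivity(tl, exp, what = "walking")
  expect_equal(unname(m[1, "h5"]), 270 * 60)
  mr <- hourlyActivity(tl, exp, what = "resting")
  expect_equal(unname(mr[1, "h5"]), 30 * 60)
})

test_that("circadian profiles normalize as requested", {
  flat <- matrix(5, nrow = 3, ncol = 24)
  pShare <- circadianProfile(flat, "share")
  expect_equal(as.numeric(pShare), rep(1 / 24, 24))
  expect_equal(sum(pShare), 1)
  pPeak <- circadianProfile(flat, "peak")
  expect_equal(max(pPeak), 1)

  withGap <- flat
  withGap[, 3] <- NA
  pg <- circadianProfile(withGap, "share")
  expect_true(is.na(pg[3]))
  expect_equal(sum(pg, na.rm = TRUE), 1)

  expect_equal(hourBlockShare(pShare, 7:18), 12 / 24)
})

test_that("age profiles average living flies and peak-normalize", {
  m1 <- matrix(1, nrow = 4, ncol = 24)   # constant fly, alive 4 days
  m2 <- matrix(2, nrow = 2, ncol = 24)   # dies after day 2
  ap <- ageProfile(list(m1, m2))
  expect_equal(ap$value, c(36, 36, 24, 24))
  apPk <- ageProfile(list(m1, m2), "peak")
  expect_equal(max(apPk$value), 1)

  single <- ageProfile(m1)
  expect_true(all(single$value == single$value[1]))
})

test_that("top occupancy is the fraction of frames in the cage top", {
  g <- cageGeometry()
  top <- syntheticBoutFrames(0, 0); top$z <- g@height
  expect_equal(unname(topOccupancy(top, g, exp)[1]), 1)
  floor_ <- syntheticBoutFrames(0, 0); floor_$z <- 0
  expect_equal(unname(topOccupancy(floor_, g, exp)[1]), 0)
  half <- syntheticBoutFrames(0, 0)
  half$z <- rep(c(0, g@height), 150)
  expect_equal(unname(topOccupancy(half, g, exp)[1]), 0.5)
})

test_that("rest runs are binned into the four duration classes", {
  cfg <- classifierConfig()
  expect_equal(restRuns(restRunTimeline(90 * 60), cfg)$bin, "1-2")
  expect_equal(restRuns(restRunTimeline(30 * 60), cfg)$bin, "<1")
  expect_equal(restRuns(restRunTimeline(2.5 * 3600), cfg)$bin, "2-3")
  expect_equal(restRuns(restRunTimeline(4 * 3600), cfg)$bin, ">3")

  # one active frame splits a run in two
  tl <- restRunTimeline(2 * 3600)
  mid <- which.min(abs(tl$t - 4 * 3600))
  tl$label[mid] <- "walking"
  expect_identical(nrow(restRuns(tl, cfg)), 2L)
})

test_that("event-history rasters code presence, absence and gaps", {
  tl <- syntheticBoutFrames(3600 * 8, 10, label = "resting")
  tl$label[5] <- "walking"
  m <- eventHistory(tl, "walking", exp)
  expect_equal(unname(m[1, "h8"]), 1L)
  expect_true(is.na(m[1, "h9"]))

  m2 <- eventHistory(tl, "flying", exp)
  expect_equal(unname(m2[1, "h8"]), 0L)

  tl3 <- rbind(tl, syntheticBoutFrames(86400 * 2 + 3600, 5, "b9"))
  expect_identical(nrow(eventHistory(tl3, "walking", exp)), 3L)
})

test_that("behavior frequencies are normalized shares over the interval", {
  tl <- syntheticBoutFrames(0, 0, label = "resting")
  v <- behaviorFrequencies(tl, c(1, 2), exp)
  expect_equal(unname(v), c(1, 0, 0, 0, 0, 0))

  tl$label <- rep(behaviorLabels(), 50)
  v2 <- behaviorFrequencies(tl, c(1, 2), exp)
  expect_equal(unname(v2), rep(1 / 6, 6))
  expect_equal(sum(v2), 1)

  expect_null(behaviorFrequencies(tl, c(30, 40), exp))
})

test_that("survival curves step down at deaths and respect censoring", {
  man <- data.frame(flyId = c("a", "b"), deathDay = c(10, 20),
                    horizonDays = 134)
  s <- survivalFromDeaths(man)
  expect_equal(s$surv[s$day == 10], 0.5)
  expect_equal(s$surv[s$day == 20], 0)
  expect_true(all(diff(s$surv) <= 0))

  cens <- data.frame(flyId = c("a", "b"), deathDay = NA_real_,
                     horizonDays = 134)
  expect_true(all(survivalFromDeaths(cens)$surv == 1))
})
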