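test_that("identical seeds give identical trajectories and cohorts", {
  a <- simulateLifetime(horizonS = 300, seed = 5, startHour = 16, startDay = 10)
  b <- simulateLifetime(horizonS = 300, seed = 5, startHour = 16, startDay = 10)
  expect_identical(a@path, b@path)

  c1 <- generateCohort(nFlies = 2, days = 0.1, seed = 3)
  c2 <- generateCohort(nFlies = 2, days = 0.1, seed = 3)
  expect_identical(c1@frames, c2@frames)
  expect_false(identical(
    c1@frames,
    generateCohort(nFlies = 2, days = 0.1, seed = 4)@frames))
})

test_that("zero activity weights leave the fly resting with zero path length", {
  quiet <- simConfig(hourlyWeights = rep(0, 24), restingSd = 0)
  tr <- simulateLifetime(quiet, horizonS = 600, seed = 1)
  expect_true(all(tr@path$state == "resting"))
  expect_equal(sum(sqrt(rowSums(diff(as.matrix(tr@path[, c("x", "y", "z")]))^2))),
               0)

  # with default tremor the path length stays at sensor-noise scale
  quiet2 <- simConfig(hourlyWeights = rep(0, 24))
  tr2 <- simulateLifetime(quiet2, horizonS = 600, seed = 1)
  steps <- sqrt(rowSums(diff(as.matrix(tr2@path[, c("x", "y", "z")]))^2))
  expect_lt(max(steps), classifierConfig()@deltaRest / 10)
})

test_that("episode dwell times converge to their configured means", {
  sim <- simConfig(stateProbs = c(micro_movement = 0.4, walking = 0.4,
                                  flying = 0.2, feeding = 0, drinking = 0))
  dur <- list(micro_movement = c(), walking = c(), flying = c())
  for (seed in 1:8) {
    tr <- simulateLifetime(sim, horizonS = 3600, seed = seed,
                           startHour = 18, startDay = 18)
    r <- rle(tr@path$state)
    for (s in names(dur)) {
      runs <- r$lengths[r$values == s] * sim@stepS
      # drop runs clipped by the horizon
      dur[[s]] <- c(dur[[s]], runs)
    }
  }
  for (s in names(dur)) {
    m <- mean(dur[[s]])
    se <- stats::sd(dur[[s]]) / sqrt(length(dur[[s]]))
    expect_lt(abs(m - sim@dwellMeans[[s]]), 3 * se + sim@stepS,
              label = sprintf("dwell mean for %s (%.2f vs %.2f)", s, m,
                              sim@dwellMeans[[s]]))
  }
})

test_that("per-step displacement is bounded by the flying scale", {
  sim <- simConfig()
  tr <- simulateLifetime(sim, horizonS = 1200, seed = 2, startHour = 17,
                         startDay = 18)
  steps <- sqrt(rowSums(diff(as.matrix(tr@path[, c("x", "y", "z")]))^2))
  expect_lt(max(steps), 3 * sim@flyingStep)
})

test_that("the round-robin schedule is periodic with the printed interval", {
  exp <- experimentConfig()
  expect_equal(perFlyIntervalS(exp), 1080)              # 18 min
  expect_equal(perFlyIntervalS(experimentConfig(cages = 1)), 120)

  sched <- scheduleBouts(exp, 86400)
  for (cg in 1:9) {
    starts <- sched$startS[sched$cage == cg]
    expect_true(all(diff(starts) == perFlyIntervalS(exp)))
  }

  # bouts per fly per hour-long window: 3 or 4 at the default pacing
  starts1 <- sched$startS[sched$cage == 1]
  counts <- sapply(seq(0, 82800, by = 600), function(o)
    sum(starts1 >= o & starts1 < o + 3600))
  expect_true(all(counts %in% c(3L, 4L)))

  # slower processing (73 s) stretches the interval towards 20 min and the
  # typical window holds 3 starts
  exp73 <- experimentConfig(processS = 73)
  s73 <- scheduleBouts(exp73, 86400)
  starts73 <- s73$startS[s73$cage == 1]
  expect_equal(perFlyIntervalS(exp73), 9 * 133)
  counts73 <- sapply(seq(0, 82800, by = 600), function(o)
    sum(starts73 >= o & starts73 < o + 3600))
  expect_true(all(counts73 %in% c(3L, 4L)))
  expect_gte(mean(counts73 == 3L), 0.9)

  # too-short horizon: empty schedule, not an error
  expect_identical(nrow(scheduleBouts(exp, 10)), 0L)
})

test_that("sampled bouts carry the expected frame counts and positions", {
  tr <- simulateLifetime(horizonS = 70, seed = 3, startHour = 18,
                         startDay = 18)
  sb <- sampleBout(tr, 0, experimentConfig())
  expect_identical(nFrames(sb$bout), 300L)
  expect_length(sb$truth, 300L)

  sb2 <- sampleBout(tr, 0, experimentConfig(rateHz = 1, boutDurationS = 10))
  expect_identical(nFrames(sb2$bout), 10L)

  quiet <- simConfig(hourlyWeights = rep(0, 24), restingSd = 0)
  still <- simulateLifetime(quiet, horizonS = 70, seed = 1)
  sb3 <- sampleBout(still, 0, experimentConfig())
  expect_equal(unname(apply(framePositions(sb3$bout), 2, stats::var)),
               c(0, 0, 0))

  expect_error(sampleBout(tr, 50, experimentConfig()), "range error")
})

test_that("displacement concentrates in lights-on hours per the weight share", {
  sim <- simConfig()
  w <- sim@hourlyWeights
  wShare <- sum(w[8:19]) / sum(w)
  shares <- sapply(1:4, function(seed) {
    tr <- simulateLifetime(sim, horizonS = 2 * 86400, seed = seed,
                           startHour = 0, startDay = 14)
    pos <- as.matrix(tr@path[, c("x", "y", "z")])
    step <- sqrt(rowSums(diff(pos)^2))
    hour <- (floor(tr@path$t[-1] / 3600)) %% 24
    sum(step[hour >= 7 & hour < 19]) / sum(step)
  })
  expect_lt(abs(mean(shares) - wShare), 0.04)
})

test_that("flies stop producing bouts after death", {
  sim <- simConfig(lifespanMeanlog = log(2), lifespanSdlog = 0.01)
  co <- generateCohort(nFlies = 1, days = 5, sim = sim, seed = 9)
  man <- cohortManifest(co)
  expect_false(is.na(man$deathDay))
  expect_lt(max(co@frames$startS) / 86400, man$deathDay + 1e-9)
  # terminal frames are frozen resting
  lastBout <- co@frames[co@frames$boutKey == max(co@frames$boutKey), ]
  expect_true(all(lastBout$truth == "resting"))
})

test_that("the age multiplier rises to its peak and then declines", {
  a <- ageActivityMultiplier(1:60)
  expect_equal(which.max(a), 18)
  expect_true(all(diff(a[1:18]) > 0))
  expect_true(all(diff(a[18:60]) < 0))
})
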