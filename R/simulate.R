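# Six-state semi-Markov behavioral simulator with diurnal and age modulation.
#
# The fly alternates between resting episodes (exponential dwell whose exit
# rate follows the hour-of-day weight profile and an age multiplier) and
# active episodes (micro-movement, walking, flying, feeding, drinking with
# exponential dwells). Feeding/drinking are teleport-free: a walking transit
# leg carries the fly to the station and another leg carries it away.
# Episode boundaries are quantized to the base step (0.2 s, the inter-frame
# period at 5 Hz) so a sampled bout sees pure single-state dynamics on every
# inter-frame transition.

#' @rdname simConfig
#' @export
setClass("SimConfig",
  representation(
    hourlyWeights = "numeric", peakActivity = "numeric", agePeakDay = "numeric",
    dwellMeans = "numeric", stateProbs = "numeric",
    restingSd = "numeric", microAmplitude = "numeric", walkingStep = "numeric",
    flyingStep = "numeric", stepS = "numeric", stationRadiusMm = "numeric",
    meanWalkLegSteps = "numeric", lifespanMeanlog = "numeric",
    lifespanSdlog = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@hourlyWeights) != 24 || any(object@hourlyWeights < 0))
    msg <- c(msg, "hourlyWeights must be 24 non-negative values")
  if (object@peakActivity <= 0 || object@peakActivity >= 1)
    msg <- c(msg, "peakActivity must lie in (0, 1)")
  nmAct <- c("micro_movement", "walking", "flying", "feeding", "drinking")
  if (!identical(names(object@dwellMeans), nmAct) || any(object@dwellMeans <= 0))
    msg <- c(msg, "dwellMeans must be positive and named for the five active states")
  if (!identical(names(object@stateProbs), nmAct) ||
      any(object@stateProbs < 0) || abs(sum(object@stateProbs) - 1) > 1e-8)
    msg <- c(msg, "stateProbs must be a probability vector over the five active states")
  if (any(c(object@microAmplitude, object@walkingStep, object@flyingStep,
            object@stepS, object@stationRadiusMm, object@meanWalkLegSteps) <= 0) ||
      object@restingSd < 0)
    msg <- c(msg, "step scales must be positive (restingSd may be zero)")
  if (object@agePeakDay <= 0) msg <- c(msg, "agePeakDay must be positive")
  if (length(msg)) msg else TRUE
})

#' Simulator configuration
#'
#' Parameters of the six-state behavioral simulator. The defaults encode the
#' diurnal and aging structure the monitor is designed to resolve: activity
#' concentrated in the light phase (lights-on carries 90% of the hourly
#' weight mass, the 15:00-19:00 block carries 50% of it, peaking at 18:00)
#' and an age multiplier `a(d) = (d/agePeakDay) exp(1 - d/agePeakDay)` that
#' rises over the first two weeks of life, peaks at `agePeakDay` (default
#' day 18) and then declines gradually.
#'
#' The hourly weights set the *target fraction of time spent active*:
#' `f(h, d) = peakActivity * (w[h]/max(w)) * a(d)`, and the resting exit
#' rate is derived by inverting the alternating-renewal occupancy,
#' `rate = f / (tauActive * (1 - f))`, so that realized activity (and hence
#' distance) shares track the weights linearly rather than saturating.
#'
#' Displacement scales are per 0.2 s step: resting is Gaussian sensor-level
#' jitter (`restingSd` per axis), micro-movement oscillates with amplitude
#' `microAmplitude` about an anchor (large per-step motion, near-zero net
#' displacement — grooming in place), walking moves in straight
#' clearance-checked legs of `walkingStep` per step, and flying in legs of
#' `flyingStep` per step (300 mm/s at default).
#'
#' @param hourlyWeights 24 relative activity weights, hour 0 to 23.
#' @param peakActivity Active time fraction at the peak hour of the peak day.
#' @param agePeakDay Day of life at which activity peaks.
#' @param dwellMeans Mean episode durations (s) of the five active states.
#' @param stateProbs Probability of each active state when leaving rest.
#' @param restingSd Per-axis positional noise sd (mm) while resting.
#' @param microAmplitude Micro-movement oscillation amplitude (mm).
#' @param walkingStep,flyingStep Per-step displacement (mm / 0.2 s).
#' @param stepS Base simulation step (s); equal to the inter-frame period so
#'   bout sampling at the default 5 Hz is lossless.
#' @param stationRadiusMm Feeding/drinking dwell anchors fall within this
#'   distance of the station center.
#' @param meanWalkLegSteps Mean straight-leg length (steps) of free walking.
#' @param lifespanMeanlog,lifespanSdlog Log-normal parameters of the death
#'   day (days); set `lifespanMeanlog = Inf` to disable mortality.
#' @return A `SimConfig` object.
#' @examples
#' simConfig()
#' @export
simConfig <- function(hourlyWeights = c(rep(1, 7), rep(6, 8), 13, 14, 16, 17,
                                        rep(1, 5)),
                      peakActivity = 0.30, agePeakDay = 18,
                      dwellMeans = c(micro_movement = 40, walking = 15,
                                     flying = 4, feeding = 90, drinking = 60),
                      stateProbs = c(micro_movement = 0.30, walking = 0.45,
                                     flying = 0.15, feeding = 0.06,
                                     drinking = 0.04),
                      restingSd = 0.002, microAmplitude = 1.8, walkingStep = 6,
                      flyingStep = 60, stepS = 0.2, stationRadiusMm = 5,
                      meanWalkLegSteps = 20,
                      lifespanMeanlog = log(60), lifespanSdlog = 0.35) {
  new("SimConfig", hourlyWeights = hourlyWeights, peakActivity = peakActivity,
      agePeakDay = agePeakDay, dwellMeans = dwellMeans, stateProbs = stateProbs,
      restingSd = restingSd, microAmplitude = microAmplitude,
      walkingStep = walkingStep, flyingStep = flyingStep, stepS = stepS,
      stationRadiusMm = stationRadiusMm, meanWalkLegSteps = meanWalkLegSteps,
      lifespanMeanlog = lifespanMeanlog, lifespanSdlog = lifespanSdlog)
}

setMethod("show", "SimConfig", function(object) {
  w <- object@hourlyWeights
  cat(sprintf(paste0("SimConfig: peak activity %g, age peak day %g, ",
                     "lights-on weight share %.1f%%\n"),
              object@peakActivity, object@agePeakDay,
              100 * sum(w[8:19]) / sum(w)))
})

#' Age activity multiplier
#'
#' `a(d) = (d / peak) * exp(1 - d / peak)`: 0 at birth, 1 at the peak day,
#' then a gradual decline.
#'
#' @param day Day of life (1-based).
#' @param sim A [simConfig()].
#' @return Multiplier in `[0, 1]`.
#' @export
ageActivityMultiplier <- function(day, sim = simConfig()) {
  p <- sim@agePeakDay
  (day / p) * exp(1 - day / p)
}

.hourOfDay <- function(t, startHour = 0) (floor(t / 3600) + startHour) %% 24

.dayOfLife <- function(t, startDay = 1) floor(t / 86400) + startDay

.activeMeanDuration <- function(sim) sum(sim@stateProbs * sim@dwellMeans)

.targetActivity <- function(sim, hour, day) {
  w <- sim@hourlyWeights
  if (max(w) == 0) return(0)
  f <- sim@peakActivity * (w[hour + 1] / max(w)) * ageActivityMultiplier(day, sim)
  min(f, 0.9)
}

.restExitRate <- function(sim, hour, day, tauA = .activeMeanDuration(sim)) {
  f <- .targetActivity(sim, hour, day)
  if (f <= 0) return(0)
  f / (tauA * (1 - f))
}

# Rest dwell under the piecewise-constant (per clock hour) exit rate.
.sampleRestDwell <- function(sim, t0, startHour, startDay, horizonS, tauA) {
  E <- rexp(1)
  t <- t0
  repeat {
    if (t >= horizonS) return(horizonS - t0)
    rate <- .restExitRate(sim, .hourOfDay(t, startHour),
                          .dayOfLife(t, startDay), tauA)
    bnd <- min((floor(t / 3600) + 1) * 3600, horizonS)
    dt <- bnd - t
    if (rate > 0 && rate * dt >= E) return(t + E / rate - t0)
    if (rate > 0) E <- E - rate * dt
    t <- bnd
  }
}

.gridRound <- function(d, stepS) max(stepS, round(d / stepS) * stepS)

.runifCage <- function(geom) {
  c(runif(1, 0, geom@width), runif(1, 0, geom@depth), runif(1, 0, geom@height))
}

.cageLims <- function(geom) c(geom@width, geom@depth, geom@height)

.foldIntoCage <- function(p, geom) {
  lim <- .cageLims(geom)
  y <- p %% (2 * lim)
  ifelse(y > lim, 2 * lim - y, y)
}

.randUnit <- function() {
  repeat {
    u <- rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-12) return(u / n)
  }
}

# Straight-line clearance from p along unit direction d, in mm.
.clearance <- function(p, d, lim) {
  cl <- Inf
  for (j in 1:3) {
    if (d[j] > 1e-12) cl <- min(cl, (lim[j] - p[j]) / d[j])
    else if (d[j] < -1e-12) cl <- min(cl, p[j] / -d[j])
  }
  cl
}

# Pick a travel direction with at least `need` mm of straight clearance,
# preferring directions that do not reverse the previous heading (keeps the
# net displacement of short windows from collapsing at walls). Falls back to
# the through-center direction, which always clears at least half the cage.
.pickDirection <- function(p, prev, need, lim) {
  for (i in 1:30) {
    d <- .randUnit()
    if (.clearance(p, d, lim) < need) next
    if (i <= 15 && !is.null(prev) && sum(d * prev) < 0) next
    return(d)
  }
  ctr <- lim / 2 - p
  n <- sqrt(sum(ctr^2))
  if (n < 1e-9) return(.randUnit())
  ctr / n
}

# --- the episode timeline ---------------------------------------------------

.EP_COLS <- c("state", "mode", "t0", "t1", "x0", "y0", "z0", "x1", "y1", "z1",
              "vx", "vy", "vz")

.stationAnchor <- function(center, radius, geom) {
  repeat {
    off <- runif(3, -radius, radius)
    off[3] <- abs(off[3]) / 2          # stations sit on the floor; stay low
    if (sqrt(sum(off^2)) <= radius) break
  }
  pmin(pmax(center + off, 0), .cageLims(geom))
}

# Generates the fly's lifetime as a contiguous sequence of behavioral
# episodes with coarse start/end positions. Exact step-level positions are
# realized later, only where needed.
.episodeTimeline <- function(sim, geom, horizonS, startHour = 0, startDay = 1,
                             deathS = NA_real_) {
  tauA <- .activeMeanDuration(sim)
  stepS <- sim@stepS
  # keep every episode boundary an exact grid double (k * stepS computed the
  # same way realization computes it), so findInterval lookups are exact
  snap <- function(x) round(x / stepS) * stepS
  if (!is.na(deathS)) deathS <- snap(deathS)
  lim <- .cageLims(geom)
  eps <- vector("list", 256L)
  nEp <- 0L
  emit <- function(state, mode, t0, t1, p0, p1, v = c(NA_real_, NA_real_, NA_real_)) {
    nEp <<- nEp + 1L
    if (nEp > length(eps)) length(eps) <<- 2L * nEp
    eps[[nEp]] <<- list(state = state, mode = mode, t0 = t0, t1 = t1,
                        x0 = p0[1], y0 = p0[2], z0 = p0[3],
                        x1 = p1[1], y1 = p1[2], z1 = p1[3],
                        vx = v[1], vy = v[2], vz = v[3])
  }
  transit <- function(t, pos, target) {
    dist <- sqrt(sum((target - pos)^2))
    dur <- max(1, ceiling(dist / sim@walkingStep)) * stepS
    dur <- min(dur, horizonS - t)
    if (dur > 0) emit("walking", "transit", t, snap(t + dur), pos, target)
    list(t = snap(t + dur), pos = target)
  }
  pos <- .runifCage(geom)
  t <- 0
  deathTime <- NA_real_
  while (t < horizonS) {
    dwell <- .gridRound(.sampleRestDwell(sim, t, startHour, startDay, horizonS,
                                         tauA), stepS)
    restEnd <- snap(min(t + dwell, horizonS))
    if (!is.na(deathS) && restEnd >= deathS) {
      deathTime <- max(t, deathS)
      if (deathTime > t) emit("resting", "rest", t, deathTime, pos, pos)
      emit("resting", "dead", deathTime, horizonS, pos, pos)
      break
    }
    emit("resting", "rest", t, restEnd, pos, pos)
    t <- restEnd
    if (t >= horizonS) break
    s <- sample(names(sim@stateProbs), 1L, prob = sim@stateProbs)
    if (s %in% c("feeding", "drinking")) {
      center <- if (s == "feeding") geom@foodCenter else geom@waterCenter
      anchor <- .stationAnchor(center, sim@stationRadiusMm, geom)
      tp <- transit(t, pos, anchor)
      t <- tp$t; pos <- tp$pos
      if (t >= horizonS) break
      dur <- min(.gridRound(rexp(1, 1 / sim@dwellMeans[[s]]), stepS), horizonS - t)
      emit(s, "station", t, snap(t + dur), pos, pos)
      t <- snap(t + dur)
      if (t >= horizonS) break
      tp <- transit(t, pos, .runifCage(geom))
      t <- tp$t; pos <- tp$pos
    } else if (s == "micro_movement") {
      dur <- min(.gridRound(rexp(1, 1 / sim@dwellMeans[[s]]), stepS), horizonS - t)
      amp <- sim@microAmplitude
      anchor <- pmin(pmax(pos, amp), lim - amp)
      v <- amp * .randUnit()
      emit(s, "micro", t, snap(t + dur), anchor, anchor, v)
      t <- snap(t + dur)
      pos <- anchor
    } else if (s == "walking") {
      dur <- min(.gridRound(rexp(1, 1 / sim@dwellMeans[[s]]), stepS), horizonS - t)
      L <- (dur / stepS) * sim@walkingStep
      end <- if (L >= 0.8 * min(lim)) .runifCage(geom)
             else .foldIntoCage(pos + L * .randUnit(), geom)
      emit(s, "walkfree", t, snap(t + dur), pos, end)
      t <- snap(t + dur)
      pos <- end
    } else {                                    # flying
      dur <- min(.gridRound(rexp(1, 1 / sim@dwellMeans[[s]]), stepS), horizonS - t)
      end <- .runifCage(geom)
      emit(s, "fly", t, snap(t + dur), pos, end)
      t <- snap(t + dur)
      pos <- end
    }
  }
  tl <- data.table::rbindlist(eps[seq_len(nEp)])
  data.table::setattr(tl, "deathTime", deathTime)
  data.table::setattr(tl, "startPos", c(tl$x0[1], tl$y0[1], tl$z0[1]))
  tl
}

# --- step-level realization -------------------------------------------------

# Positions at grid instants strictly inside one episode's (t0, t1].
# `phases` are 1-based step indices relative to the episode start; `p0` is
# the realized position at the episode's start (chained from the previous
# episode so trajectories stay continuous). Returns the sampled positions
# and the realized endpoint of the episode.
.realizeEpisode <- function(ep, p0, phases, sim, geom) {
  n <- length(phases)
  lim <- .cageLims(geom)
  clampCage <- function(m) {
    m[, 1] <- pmin(pmax(m[, 1], 0), lim[1])
    m[, 2] <- pmin(pmax(m[, 2], 0), lim[2])
    m[, 3] <- pmin(pmax(m[, 3], 0), lim[3])
    m
  }
  totalPhases <- as.integer(round((ep$t1 - ep$t0) / sim@stepS))
  switch(ep$mode,
    rest = ,
    station = list(
      pos = clampCage(matrix(p0, n, 3, byrow = TRUE) +
                        matrix(rnorm(3 * n, sd = sim@restingSd), n, 3)),
      end = p0),
    dead = list(pos = matrix(p0, n, 3, byrow = TRUE), end = p0),
    micro = {
      amp <- sqrt(ep$vx^2 + ep$vy^2 + ep$vz^2)
      anchor <- pmin(pmax(p0, amp), lim - amp)
      v <- c(ep$vx, ep$vy, ep$vz)
      sgn <- ifelse(phases %% 2 == 1, 1, -1)
      list(pos = clampCage(matrix(anchor, n, 3, byrow = TRUE) + outer(sgn, v) +
                             matrix(rnorm(3 * n, sd = 0.05), n, 3)),
           end = anchor)
    },
    transit = {
      p1 <- c(ep$x1, ep$y1, ep$z1)
      dist <- sqrt(sum((p1 - p0)^2))
      u <- if (dist > 1e-12) (p1 - p0) / dist else c(0, 0, 0)
      s <- pmin(phases * sim@walkingStep, dist)
      list(pos = matrix(p0, n, 3, byrow = TRUE) + outer(s, u), end = p1)
    },
    walkfree = {
      path <- matrix(NA_real_, totalPhases, 3)
      p <- p0; prev <- NULL; k <- 0L
      need <- 4 * sim@walkingStep
      while (k < totalPhases) {
        d <- .pickDirection(p, prev, need, lim)
        clearSteps <- floor(.clearance(p, d, lim) / sim@walkingStep)
        legLen <- min(totalPhases - k, clearSteps,
                      1L + stats::rgeom(1, 1 / sim@meanWalkLegSteps))
        legLen <- max(1L, legLen)
        leg <- matrix(p, legLen, 3, byrow = TRUE) +
          outer(seq_len(legLen) * sim@walkingStep, d)
        path[k + seq_len(legLen), ] <- leg
        p <- leg[legLen, ]
        prev <- d
        k <- k + legLen
      }
      path <- clampCage(path)
      list(pos = path[phases, , drop = FALSE], end = path[totalPhases, ])
    },
    fly = {
      path <- matrix(NA_real_, totalPhases, 3)
      p <- p0
      for (k in seq_len(totalPhases)) {
        for (i in 1:50) {
          d <- .randUnit()
          q <- p + sim@flyingStep * d
          if (all(q >= 0) && all(q <= lim)) break
          if (i == 50) {
            ctr <- lim / 2 - p
            q <- p + sim@flyingStep * ctr / sqrt(sum(ctr^2))
          }
        }
        path[k, ] <- q
        p <- q
      }
      path <- clampCage(path)
      list(pos = path[phases, , drop = FALSE], end = path[totalPhases, ])
    },
    stop(sprintf("unknown episode mode '%s'", ep$mode))
  )
}

# Positions + true labels at ascending grid instants of a timeline. Episodes
# touched by the instants are realized in order, each starting from the
# previous one's realized endpoint (adjacent episodes only; across a gap the
# stored episode-level position is used).
.realizeInstants <- function(tl, instants, sim, geom) {
  idx <- findInterval(instants - 1e-9, tl$t0)
  pos <- matrix(NA_real_, length(instants), 3)
  state <- character(length(instants))
  atStart <- idx == 0L
  if (any(atStart)) {
    sp <- attr(tl, "startPos")
    pos[atStart, ] <- matrix(sp, sum(atStart), 3, byrow = TRUE)
    state[atStart] <- tl$state[1]
  }
  lastEp <- -1L
  chainEnd <- NULL
  for (i in sort(unique(idx[!atStart]))) {
    sel <- which(idx == i)
    ep <- as.list(tl[i, ])
    p0 <- if (i == lastEp + 1L && !is.null(chainEnd)) chainEnd
          else c(ep$x0, ep$y0, ep$z0)
    phases <- as.integer(round((instants[sel] - ep$t0) / sim@stepS))
    r <- .realizeEpisode(ep, p0, phases, sim, geom)
    pos[sel, ] <- r$pos
    state[sel] <- ep$state
    lastEp <- i
    chainEnd <- r$end
  }
  list(pos = pos, state = state, dead = tl$mode[pmax(idx, 1L)] == "dead")
}

# --- exported simulation operations ----------------------------------------

#' @rdname simulateLifetime
#' @export
setClass("TrueTrajectory",
  representation(path = "data.frame", deathTime = "numeric",
                 geometry = "CageGeometry", stepS = "numeric")
)

setMethod("show", "TrueTrajectory", function(object) {
  cat(sprintf("TrueTrajectory: %d steps of %g s (%.1f h)%s\n",
              nrow(object@path), object@stepS,
              nrow(object@path) * object@stepS / 3600,
              if (is.na(object@deathTime)) ""
              else sprintf(", death at %.1f h", object@deathTime / 3600)))
})

#' Simulate a fly's ground-truth trajectory
#'
#' Runs the six-state semi-Markov simulator and realizes the dense path at
#' the base step (0.2 s by default): a data frame of `(t, x, y, z, state)`
#' rows. Intended for horizons up to a few days; lifetime-scale cohorts
#' should use [generateCohort()], which realizes positions only inside
#' scheduled recording bouts.
#'
#' @param sim A [simConfig()].
#' @param geometry A [cageGeometry()].
#' @param horizonS Simulated span in seconds.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param startHour Clock hour at `t = 0`.
#' @param startDay Day of life at `t = 0` (sets the age multiplier).
#' @param deathS Optional death time (seconds); the fly enters a terminal
#'   frozen resting state at the start of the first rest at or after it.
#' @return A `TrueTrajectory`.
#' @examples
#' tr <- simulateLifetime(horizonS = 120, seed = 1, startHour = 18,
#'                        startDay = 18)
#' head(tr@path)
#' @export
simulateLifetime <- function(sim = simConfig(), geometry = cageGeometry(),
                             horizonS = 3600, seed = NULL, startHour = 0,
                             startDay = 1, deathS = NA_real_) {
  if (!is.null(seed)) set.seed(seed)
  tl <- .episodeTimeline(sim, geometry, horizonS, startHour, startDay, deathS)
  instants <- seq(sim@stepS, by = sim@stepS,
                  length.out = floor(horizonS / sim@stepS + 1e-9))
  r <- .realizeInstants(tl, instants, sim, geometry)
  sp <- attr(tl, "startPos")
  path <- data.frame(t = c(0, instants),
                     x = c(sp[1], r$pos[, 1]), y = c(sp[2], r$pos[, 2]),
                     z = c(sp[3], r$pos[, 3]),
                     state = c(tl$state[1], r$state))
  new("TrueTrajectory", path = path,
      deathTime = as.numeric(attr(tl, "deathTime")), geometry = geometry,
      stepS = sim@stepS)
}

#' Round-robin bout schedule
#'
#' Enumerates the acquisition schedule: cage 1 records for `boutDurationS`
#' seconds, then `processS` seconds of processing, then cage 2, and so on;
#' after the last cage the cycle restarts. Each fly is therefore revisited
#' every `cages * (boutDurationS + processS)` seconds (1080 s = 18 min at
#' the defaults).
#'
#' @param exp An [experimentConfig()].
#' @param horizonS Schedule horizon in seconds; only bouts that complete by
#'   the horizon are listed (a horizon too short for one bout gives an empty
#'   schedule, not an error).
#' @return data.frame with columns `cage` (1-based) and `startS`.
#' @examples
#' head(scheduleBouts(experimentConfig(), 7200))
#' @export
scheduleBouts <- function(exp = experimentConfig(), horizonS) {
  slot <- exp@boutDurationS + exp@processS
  starts <- seq(0, by = slot, length.out =
                  max(0, floor((horizonS - exp@boutDurationS) / slot) + 1))
  starts <- starts[starts + exp@boutDurationS <= horizonS]
  data.frame(cage = as.integer((seq_along(starts) - 1L) %% exp@cages + 1L),
             startS = starts)
}

#' @rdname scheduleBouts
#' @details `perFlyIntervalS()` returns the fixed revisit interval of one
#'   fly under the schedule, in seconds.
#' @export
perFlyIntervalS <- function(exp = experimentConfig()) {
  exp@cages * (exp@boutDurationS + exp@processS)
}

#' Sample a recording bout from a dense trajectory
#'
#' Picks the trajectory point nearest each sampling instant and emits an
#' unlabeled [bout()] together with the retained ground-truth label
#' sequence.
#'
#' @param truth A [simulateLifetime()] result.
#' @param startS Bout start (seconds within the trajectory span).
#' @param exp An [experimentConfig()] (sampling rate and bout length).
#' @param flyId,cageId Identifiers stamped on the bout.
#' @return A list with elements `bout` (labels unset) and `truth`
#'   (character vector of ground-truth labels per frame).
#' @export
sampleBout <- function(truth, startS, exp = experimentConfig(),
                       flyId = "f1", cageId = "c1") {
  n <- round(exp@rateHz * exp@boutDurationS)
  instants <- startS + (seq_len(n) - 1L) / exp@rateHz
  path <- truth@path
  if (startS < path$t[1] || max(instants) > path$t[nrow(path)] + 1e-9)
    stop("range error: bout extends past the trajectory span")
  idx <- pmin(pmax(round(instants / truth@stepS) + 1L, 1L), nrow(path))
  fr <- data.frame(t = instants - startS, x = path$x[idx], y = path$y[idx],
                   z = path$z[idx], label = NA_character_)
  list(bout = bout(flyId, cageId, startS, exp@rateHz, exp@boutDurationS, fr,
                   truth@geometry),
       truth = path$state[idx])
}

.deriveSeed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + i * 7919) %% 2147483647L) + 1L
}
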