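#' @import methods
#' @importFrom stats rnorm rexp runif setNames dist hclust cutree as.dist
#' @importFrom utils head tail
NULL

#' Behavior label vocabulary
#'
#' The six classifiable behaviors, in their canonical order, plus the
#' single-letter codes used in bout-log files. The sentinels `no_data` and
#' `dead` appear only in summaries, never inside a classified bout.
#'
#' @return `behaviorLabels()` returns a character vector of the six labels;
#'   `behaviorCodes()` returns the named single-letter code map.
#' @examples
#' behaviorLabels()
#' behaviorCodes()
#' @export
behaviorLabels <- function() {
  c("resting", "micro_movement", "walking", "flying", "feeding", "drinking")
}

#' @rdname behaviorLabels
#' @export
behaviorCodes <- function() {
  setNames(c("R", "M", "W", "F", "E", "D"), behaviorLabels())
}

.labelFromCode <- function(code) {
  map <- setNames(names(behaviorCodes()), behaviorCodes())
  out <- map[code]
  out[code == "-"] <- NA_character_
  unname(out)
}

# ---------------------------------------------------------------------------
# CageGeometry
# ---------------------------------------------------------------------------

#' @rdname cageGeometry
#' @export
setClass("CageGeometry",
  representation(
    width = "numeric", depth = "numeric", height = "numeric",
    foodCenter = "numeric", waterCenter = "numeric",
    topFraction = "numeric"
  )
)

setValidity("CageGeometry", function(object) {
  msg <- character()
  if (any(c(object@width, object@depth, object@height) <= 0))
    msg <- c(msg, "cage dimensions must be positive")
  for (nm in c("foodCenter", "waterCenter")) {
    p <- slot(object, nm)
    if (length(p) != 3) msg <- c(msg, sprintf("%s must be length-3 (x, y, z)", nm))
    else {
      if (p[3] != 0) msg <- c(msg, sprintf("%s must sit on the cage floor (z = 0)", nm))
      if (!.insideCage(p, object)) msg <- c(msg, sprintf("%s outside the cage", nm))
    }
  }
  if (length(object@foodCenter) == 3 && length(object@waterCenter) == 3 &&
      all(object@foodCenter == object@waterCenter))
    msg <- c(msg, "foodCenter and waterCenter must differ")
  if (object@topFraction <= 0 || object@topFraction >= 1)
    msg <- c(msg, "topFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

.insideCage <- function(p, geom, tol = 1e-9) {
  all(p >= -tol) && p[1] <= geom@width + tol &&
    p[2] <= geom@depth + tol && p[3] <= geom@height + tol
}

#' Cage geometry
#'
#' Describes one monitoring cage: a rectangular box (origin at the
#' front-bottom-left corner, z pointing up, all lengths in mm) with fixed
#' food and water stations on the floor and a "top of the cage" region used
#' for location-preference summaries.
#'
#' @param width,depth,height Cage dimensions in mm.
#' @param foodCenter,waterCenter Length-3 positions (mm) of the feeding and
#'   drinking stations; both must lie on the floor (z = 0).
#' @param topFraction Fraction of the cage height counted as the top region:
#'   a point is "at the top" when `z >= (1 - topFraction) * height`.
#' @return A `CageGeometry` object.
#' @examples
#' geom <- cageGeometry()
#' inTopRegion(c(75, 75, 140), geom)
#' @export
cageGeometry <- function(width = 150, depth = 150, height = 150,
                         foodCenter = c(40, 40, 0),
                         waterCenter = c(110, 110, 0),
                         topFraction = 0.25) {
  new("CageGeometry", width = width, depth = depth, height = height,
      foodCenter = as.numeric(foodCenter), waterCenter = as.numeric(waterCenter),
      topFraction = topFraction)
}

#' @param p A length-3 position or an n x 3 matrix of positions (mm).
#' @param geom A [cageGeometry()] object.
#' @rdname cageGeometry
#' @export
inTopRegion <- function(p, geom) {
  z <- if (is.matrix(p)) p[, 3] else p[3]
  z >= (1 - geom@topFraction) * geom@height
}

setMethod("show", "CageGeometry", function(object) {
  cat(sprintf("CageGeometry %g x %g x %g mm; food (%s), water (%s); top %g%%\n",
              object@width, object@depth, object@height,
              paste(object@foodCenter, collapse = ", "),
              paste(object@waterCenter, collapse = ", "),
              100 * object@topFraction))
})

# ---------------------------------------------------------------------------
# ClassifierConfig
# ---------------------------------------------------------------------------

#' @rdname classifierConfig
#' @export
setClass("ClassifierConfig",
  representation(
    deltaRest = "numeric", deltaWalk = "numeric", deltaFly = "numeric",
    windowN = "integer", feedMinPoints = "integer",
    feedRadius = "numeric", drinkRadius = "numeric", deathHours = "numeric"
  )
)

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (!(object@deltaRest > 0 && object@deltaRest < object@deltaWalk &&
        object@deltaWalk < object@deltaFly))
    msg <- c(msg, "need 0 < deltaRest < deltaWalk < deltaFly")
  if (object@windowN < 2L) msg <- c(msg, "windowN must be >= 2")
  if (object@feedMinPoints < 1L) msg <- c(msg, "feedMinPoints must be >= 1")
  if (object@feedRadius <= 0 || object@drinkRadius <= 0)
    msg <- c(msg, "station radii must be positive")
  if (object@deathHours <= 0) msg <- c(msg, "deathHours must be positive")
  if (length(msg)) msg else TRUE
})

#' Classifier configuration
#'
#' Thresholds for the rule-based behavior classifier. All distances are in
#' mm of 3D displacement between consecutive video frames (0.2 s apart at
#' the default 5 Hz).
#'
#' @param deltaRest Resting threshold: a frame-to-frame displacement at or
#'   below this is resting.
#' @param deltaWalk Walking threshold: a tumbling window of `windowN` frames
#'   whose net (first-to-last) displacement is at or below this has its
#'   unresolved frames labeled micro-movement, otherwise walking.
#' @param deltaFly Flying threshold: a displacement at or above this is flying.
#' @param windowN Frames per tumbling window used by the micro/walk rule.
#' @param feedMinPoints Minimum length (frames) of a resting run near a
#'   station for it to be relabeled feeding/drinking.
#' @param feedRadius,drinkRadius Station radii in mm. The two station disks
#'   must not overlap (feeding takes precedence is thereby never needed).
#' @param deathHours Continuous resting duration (hours) that flags death.
#' @return A `ClassifierConfig` object.
#' @examples
#' classifierConfig()
#' @export
classifierConfig <- function(deltaRest = 1, deltaWalk = 5, deltaFly = 20,
                             windowN = 5L, feedMinPoints = 25L,
                             feedRadius = 10, drinkRadius = 10,
                             deathHours = 5) {
  new("ClassifierConfig", deltaRest = deltaRest, deltaWalk = deltaWalk,
      deltaFly = deltaFly, windowN = as.integer(windowN),
      feedMinPoints = as.integer(feedMinPoints), feedRadius = feedRadius,
      drinkRadius = drinkRadius, deathHours = deathHours)
}

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf(paste0(
    "ClassifierConfig: rest <= %g mm, fly >= %g mm, walk window net > %g mm ",
    "(N = %d)\n  stations: >= %d frames within %g/%g mm; death: %g h rest\n"),
    object@deltaRest, object@deltaFly, object@deltaWalk, object@windowN,
    object@feedMinPoints, object@feedRadius, object@drinkRadius,
    object@deathHours))
})

# ---------------------------------------------------------------------------
# ExperimentConfig
# ---------------------------------------------------------------------------

#' @rdname experimentConfig
#' @export
setClass("ExperimentConfig",
  representation(
    cages = "integer", rateHz = "numeric", boutDurationS = "numeric",
    processS = "numeric", lightsOnHour = "numeric", lightsOffHour = "numeric",
    start = "POSIXct"
  )
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (object@cages < 1L) msg <- c(msg, "cages must be >= 1")
  if (object@rateHz <= 0) msg <- c(msg, "rateHz must be positive")
  if (object@boutDurationS <= 0) msg <- c(msg, "boutDurationS must be positive")
  if (object@processS < 0) msg <- c(msg, "processS must be non-negative")
  if (!(object@lightsOnHour >= 0 && object@lightsOnHour < object@lightsOffHour &&
        object@lightsOffHour <= 24))
    msg <- c(msg, "need 0 <= lightsOnHour < lightsOffHour <= 24")
  if (length(msg)) msg else TRUE
})

#' Acquisition configuration
#'
#' The round-robin acquisition schedule of the monitor: each of `cages`
#' cages is recorded in turn for `boutDurationS` seconds at `rateHz` frames
#' per second, followed by `processS` seconds of on-line processing before
#' the next cage starts. With the defaults (9 cages, 60 s record + 60 s
#' process) each fly is revisited every 18 minutes.
#'
#' @param cages Number of cages monitored round-robin.
#' @param rateHz Sampling rate in frames per second.
#' @param boutDurationS Length of one recording bout in seconds.
#' @param processS Dead time after each bout, in seconds.
#' @param lightsOnHour,lightsOffHour Clock hours of the light cycle.
#' @param start Experiment start datetime (`POSIXct`); defaults to a
#'   midnight so that days of life align with calendar days.
#' @return An `ExperimentConfig` object.
#' @examples
#' experimentConfig()
#' @export
experimentConfig <- function(cages = 9L, rateHz = 5, boutDurationS = 60,
                             processS = 60, lightsOnHour = 7,
                             lightsOffHour = 19,
                             start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  new("ExperimentConfig", cages = as.integer(cages), rateHz = rateHz,
      boutDurationS = boutDurationS, processS = processS,
      lightsOnHour = lightsOnHour, lightsOffHour = lightsOffHour,
      start = start)
}

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf(paste0(
    "ExperimentConfig: %d cages, %g Hz x %g s bouts (+%g s processing), ",
    "lights %02d:00-%02d:00\n  start %s\n"),
    object@cages, object@rateHz, object@boutDurationS, object@processS,
    object@lightsOnHour, object@lightsOffHour,
    format(object@start, "%Y-%m-%d %H:%M:%S %Z")))
})

# ---------------------------------------------------------------------------
# Bout / Ethogram
# ---------------------------------------------------------------------------

#' @rdname bout
#' @export
setClass("Bout",
  representation(
    flyId = "character", cageId = "character", startTime = "numeric",
    rateHz = "numeric", durationS = "numeric", frames = "data.frame",
    geometry = "CageGeometry"
  )
)

setValidity("Bout", function(object) {
  msg <- character()
  fr <- object@frames
  need <- c("t", "x", "y", "z", "label")
  if (!all(need %in% names(fr)))
    return(sprintf("frames must have columns %s", paste(need, collapse = ", ")))
  nExp <- round(object@rateHz * object@durationS)
  if (nrow(fr) != nExp)
    msg <- c(msg, sprintf("frame count %d != rateHz x durationS = %d", nrow(fr), nExp))
  if (nrow(fr) > 1) {
    dt <- diff(fr$t)
    if (any(dt <= 0) || max(abs(dt - 1 / object@rateHz)) > 1e-6)
      msg <- c(msg, "frame times must increase by the sampling period")
  }
  pos <- as.matrix(fr[, c("x", "y", "z")])
  g <- object@geometry
  if (any(pos < -1e-9) || any(pos[, 1] > g@width + 1e-9) ||
      any(pos[, 2] > g@depth + 1e-9) || any(pos[, 3] > g@height + 1e-9))
    msg <- c(msg, "positions outside the cage")
  bad <- !is.na(fr$label) & !fr$label %in% behaviorLabels()
  if (any(bad)) msg <- c(msg, "labels must be one of the six behaviors or NA")
  if (length(msg)) msg else TRUE
})

#' A single recording bout
#'
#' One contiguous recording of a single fly: `round(rateHz * durationS)`
#' frames, each a timestamped 3D position (mm, cage frame) with an optional
#' behavior label.
#'
#' @param flyId,cageId Identifiers.
#' @param startTime Bout start in seconds since experiment start.
#' @param rateHz Frames per second.
#' @param durationS Bout length in seconds.
#' @param frames data.frame with columns `t` (seconds from bout start),
#'   `x`, `y`, `z` (mm) and `label` (behavior or `NA`).
#' @param geometry The [cageGeometry()] the positions live in.
#' @return A `Bout` object.
#' @examples
#' b <- makeStationaryBout(nFrames = 10)
#' nFrames(b)
#' @export
bout <- function(flyId, cageId, startTime, rateHz, durationS, frames,
                 geometry = cageGeometry()) {
  frames$label <- as.character(frames$label)
  new("Bout", flyId = as.character(flyId), cageId = as.character(cageId),
      startTime = startTime, rateHz = rateHz, durationS = durationS,
      frames = frames, geometry = geometry)
}

#' @param object,b A `Bout`.
#' @rdname bout
#' @export
nFrames <- function(b) nrow(b@frames)

#' @rdname bout
#' @export
framePositions <- function(b) as.matrix(b@frames[, c("x", "y", "z")])

#' @rdname bout
#' @export
frameTimes <- function(b) b@frames$t + b@startTime

#' @rdname bout
#' @export
frameLabels <- function(b) b@frames$label

setMethod("show", "Bout", function(object) {
  cat(sprintf("Bout fly %s / cage %s: %d frames @ %g Hz, start t = %g s\n",
              object@flyId, object@cageId, nFrames(object), object@rateHz,
              object@startTime))
})

#' A convenience constructor for a motionless bout (used in examples/tests)
#'
#' @param nFrames Number of frames.
#' @param at Length-3 position held throughout.
#' @param rateHz,startTime,flyId,cageId,geometry Passed to [bout()].
#' @return A `Bout` with all frames at one position and no labels.
#' @export
makeStationaryBout <- function(nFrames = 300L, at = c(75, 75, 75), rateHz = 5,
                               startTime = 0, flyId = "f1", cageId = "c1",
                               geometry = cageGeometry()) {
  n <- as.integer(nFrames)
  bout(flyId, cageId, startTime, rateHz, n / rateHz,
       data.frame(t = (seq_len(n) - 1) / rateHz, x = at[1], y = at[2],
                  z = at[3], label = NA_character_),
       geometry)
}

#' @rdname classifyBout
#' @export
setClass("Ethogram",
  representation(labels = "character", boutRef = "Bout")
)

setValidity("Ethogram", function(object) {
  if (length(object@labels) != nFrames(object@boutRef))
    return("label count must equal the bout's frame count")
  if (!all(object@labels %in% behaviorLabels()))
    return("every frame must carry one of the six behaviors")
  TRUE
})

#' @param object An `Ethogram`.
#' @rdname classifyBout
#' @export
setMethod("show", "Ethogram", function(object) {
  tab <- table(factor(object@labels, levels = behaviorLabels()))
  cat(sprintf("Ethogram of %d frames: %s\n", length(object@labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
})

#' @param e An `Ethogram`.
#' @rdname classifyBout
#' @export
ethogramLabels <- function(e) e@labels
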