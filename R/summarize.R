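# Lifetime descriptive analytics. All operations consume a classified fly
# timeline (columns t, x, y, z, label, boutKey; absolute seconds) or a
# cohort, and report by day of life and clock hour. Because only 2-3
# one-minute bouts exist per hour, hourly cells are scaled by
# 3600 / (seconds actually recorded in the cell) to estimate full-hour
# values; hours with no recording are NA (no data).

.clockHour <- function(t, exp) (floor(t / 3600) + as.POSIXlt(exp@start)$hour) %% 24

.lifeDay <- function(t, exp) {
  floor((t + as.POSIXlt(exp@start)$hour * 3600) / 86400) + 1
}

#' Total distance traveled in a bout
#'
#' Sum of consecutive-frame displacements, in mm.
#'
#' @param b A [bout()] with at least 2 frames.
#' @return Distance in mm.
#' @examples
#' boutDistance(makeStationaryBout(10))
#' @export
boutDistance <- function(b) sum(pairDisplacements(b))

#' Hourly activity matrix (day of life x clock hour)
#'
#' For each (day, hour) cell, sums the quantity of interest over the frames
#' recorded in that cell and scales by `3600 / recorded seconds` to estimate
#' the full-hour value. `what = "distance"` sums inter-frame displacements
#' (assigned to the later frame's cell); `what = <behavior>` counts frames
#' carrying that label. Cells with no recording are `NA`.
#'
#' @param timeline A fly timeline ([flyTimeline()]).
#' @param exp The [experimentConfig()] (sampling rate and start clock).
#' @param what `"distance"` or one of [behaviorLabels()].
#' @param estimateFullHour Scale each cell by `3600 / recorded seconds`
#'   (default); `FALSE` leaves raw per-cell sums, whose total equals the sum
#'   of bout distances exactly.
#' @return Numeric matrix, rows = days of life (1..last recorded day),
#'   columns = hours `"h0" .. "h23"`.
#' @export
hourlyActivity <- function(timeline, exp = experimentConfig(),
                           what = "distance", estimateFullHour = TRUE) {
  if (!nrow(timeline)) stop("validation error: empty timeline")
  if (is.unsorted(timeline$t, strictly = TRUE))
    stop("validation error: overlapping or unordered bouts")
  dt <- data.table::as.data.table(timeline)
  dt[, `:=`(day = .lifeDay(t, exp), hour = .clockHour(t, exp))]
  if (identical(what, "distance")) {
    pos <- as.matrix(dt[, c("x", "y", "z")])
    step <- sqrt(rowSums(diff(pos)^2))
    sameBout <- dt$boutKey[-1L] == dt$boutKey[-nrow(dt)]
    dt[, value := c(0, ifelse(sameBout, step, 0))]   # later-frame assignment
  } else {
    stopifnot(what %in% behaviorLabels())
    dt[, value := as.numeric(label == what)]
  }
  cells <- dt[, list(total = sum(value), recordedS = .N / exp@rateHz),
              by = c("day", "hour")]
  nd <- max(cells$day)
  m <- matrix(NA_real_, nd, 24, dimnames = list(seq_len(nd), paste0("h", 0:23)))
  m[cbind(cells$day, cells$hour + 1L)] <-
    if (estimateFullHour) cells$total * 3600 / cells$recordedS else cells$total
  m
}

#' Hourly matrices for every fly of a cohort
#'
#' @param cohort A classified [generateCohort()] result.
#' @param what Passed to [hourlyActivity()].
#' @return Named list of matrices, one per fly.
#' @export
cohortHourlyMatrices <- function(cohort, what = "distance") {
  flies <- unique(cohort@frames$flyId)
  setNames(lapply(flies, function(f)
    hourlyActivity(flyTimeline(cohort, f), cohort@exp, what)), flies)
}

#' Circadian activity profile
#'
#' Averages each clock hour over all fly-days with data, then normalizes:
#' `"none"` leaves hourly means, `"peak"` scales the maximum to 1, and
#' `"share"` scales the 24 values to sum to 1. Hours with no data anywhere
#' stay `NA` and are excluded from the normalization.
#'
#' @param mats A matrix from [hourlyActivity()] or a list of them (a cohort).
#' @param mode Normalization mode.
#' @return Named numeric vector of 24 values with a `"mode"` attribute.
#' @export
circadianProfile <- function(mats, mode = c("none", "peak", "share")) {
  mode <- match.arg(mode)
  if (is.matrix(mats)) mats <- list(mats)
  stacked <- do.call(rbind, mats)
  v <- suppressWarnings(colMeans(stacked, na.rm = TRUE))
  v[is.nan(v)] <- NA_real_
  v <- switch(mode, none = v, peak = v / max(v, na.rm = TRUE),
              share = v / sum(v, na.rm = TRUE))
  attr(v, "mode") <- mode
  v
}

#' Share of a circadian profile falling in a clock-hour block
#'
#' @param profile A [circadianProfile()] result (any mode).
#' @param hours Integer clock hours, e.g. `7:18` for a 07:00-19:00 light
#'   phase.
#' @return Fraction in `[0, 1]`.
#' @export
hourBlockShare <- function(profile, hours) {
  sum(profile[hours + 1L], na.rm = TRUE) / sum(profile, na.rm = TRUE)
}

#' Age profile of daily activity
#'
#' Sums each fly's hourly matrix by day and averages across the flies with
#' data on that day (so flies drop out of the average after death), then
#' optionally peak-normalizes.
#'
#' @param mats List of [hourlyActivity()] matrices (one per fly).
#' @param mode `"none"` or `"peak"` (maximum scaled to 1).
#' @return data.frame with `day` and `value`.
#' @export
ageProfile <- function(mats, mode = c("none", "peak")) {
  mode <- match.arg(mode)
  if (is.matrix(mats)) mats <- list(mats)
  daily <- lapply(mats, function(m) {
    v <- rowSums(m, na.rm = TRUE)
    v[rowSums(!is.na(m)) == 0] <- NA_real_
    v
  })
  nd <- max(lengths(daily))
  acc <- sapply(daily, function(v) c(v, rep(NA_real_, nd - length(v))))
  acc <- matrix(acc, nrow = nd)
  v <- rowMeans(acc, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  if (mode == "peak") v <- v / max(v, na.rm = TRUE)
  data.frame(day = seq_len(nd), value = v)
}

#' Cage-top occupancy by clock hour
#'
#' Fraction of recorded frames whose position lies in the cage-top region,
#' per clock hour, averaged over days and then over flies.
#'
#' @param timelines One fly timeline or a list of them.
#' @param geometry A [cageGeometry()].
#' @param exp An [experimentConfig()].
#' @return Numeric vector of 24 fractions (NA where never recorded).
#' @export
topOccupancy <- function(timelines, geometry = cageGeometry(),
                         exp = experimentConfig()) {
  if (is.data.frame(timelines)) timelines <- list(timelines)
  perFly <- lapply(timelines, function(tl) {
    dt <- data.table::as.data.table(tl)
    dt[, `:=`(day = .lifeDay(t, exp), hour = .clockHour(t, exp),
              top = inTopRegion(cbind(x, y, z), geometry))]
    cells <- dt[, list(frac = mean(top)), by = c("day", "hour")]
    v <- tapply(cells$frac, factor(cells$hour, levels = 0:23), mean)
    as.numeric(v)
  })
  v <- rowMeans(do.call(cbind, perFly), na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  setNames(v, paste0("h", 0:23))
}

#' Rest (sleep-like) bout table
#'
#' Maximal resting runs of a classified timeline (chained across inter-bout
#' gaps exactly as in [detectDeath()]), with durations binned into the four
#' categories `<1`, `1-2`, `2-3` and `>3` hours.
#'
#' @param timeline A classified fly timeline.
#' @param cfg A [classifierConfig()].
#' @return data.frame with `startS`, `durationH` and `bin`.
#' @export
restRuns <- function(timeline, cfg = classifierConfig()) {
  runs <- .restingRuns(timeline$t, as.matrix(timeline[, c("x", "y", "z")]),
                       timeline$label, cfg@deltaRest)
  if (!nrow(runs))
    return(data.frame(startS = numeric(), durationH = numeric(),
                      bin = character()))
  durH <- (runs$endT - runs$startT) / 3600
  data.frame(startS = runs$startT, durationH = durH,
             bin = as.character(cut(durH, c(0, 1, 2, 3, Inf),
                                    labels = c("<1", "1-2", "2-3", ">3"),
                                    right = FALSE, include.lowest = TRUE)))
}

#' Event-history matrix for one behavior
#'
#' A day-of-life x clock-hour raster: 1 when any frame in the cell carries
#' the target behavior, 0 when the cell was recorded without it, NA when the
#' cell holds no recording. Row 1 is the youngest day.
#'
#' @param timeline A classified fly timeline.
#' @param target One of [behaviorLabels()].
#' @param exp An [experimentConfig()].
#' @return Integer matrix (days x 24) with NAs.
#' @export
eventHistory <- function(timeline, target, exp = experimentConfig()) {
  stopifnot(target %in% behaviorLabels())
  dt <- data.table::as.data.table(timeline)
  dt[, `:=`(day = .lifeDay(t, exp), hour = .clockHour(t, exp))]
  cells <- dt[, list(present = as.integer(any(label == target))),
              by = c("day", "hour")]
  nd <- max(cells$day)
  m <- matrix(NA_integer_, nd, 24, dimnames = list(seq_len(nd), paste0("h", 0:23)))
  m[cbind(cells$day, cells$hour + 1L)] <- cells$present
  m
}

#' Behavior frequency vector over an age interval
#'
#' Per-behavior share of classified frames whose day of life falls in
#' `[interval[1], interval[2])`. Shares sum to 1; returns `NULL` when the
#' interval holds no classified frames.
#'
#' @param timeline A classified fly timeline.
#' @param interval Length-2 numeric, `[startDay, endDay)`.
#' @param exp An [experimentConfig()].
#' @return Named numeric 6-vector or `NULL`.
#' @export
behaviorFrequencies <- function(timeline, interval = c(1, Inf),
                                exp = experimentConfig()) {
  day <- .lifeDay(timeline$t, exp)
  lab <- timeline$label[day >= interval[1] & day < interval[2]]
  lab <- lab[!is.na(lab)]
  if (!length(lab)) return(NULL)
  tab <- table(factor(lab, levels = behaviorLabels()))
  setNames(as.numeric(tab) / length(lab), behaviorLabels())
}

#' Survival curve from a cohort manifest
#'
#' Right-continuous Kaplan-Meier step function of the fraction of flies
#' alive by day; flies without a death day are censored at their horizon.
#'
#' @param manifest A data.frame with `deathDay` (NA = censored) and
#'   `horizonDays` columns, e.g. [cohortManifest()].
#' @return data.frame with `day` and `surv`, starting at `(0, 1)`.
#' @export
survivalFromDeaths <- function(manifest) {
  stopifnot(nrow(manifest) >= 1)
  time <- ifelse(is.na(manifest$deathDay), manifest$horizonDays,
                 manifest$deathDay)
  status <- as.integer(!is.na(manifest$deathDay))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  data.frame(day = c(0, fit$time), surv = c(1, fit$surv))
}
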