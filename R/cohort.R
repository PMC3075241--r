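# Lifetime cohorts. A FlyCohort holds every sampled frame of every fly as
# one long table plus a manifest of death/censoring. generateCohort() walks
# each fly's episode timeline chronologically and realizes exact step-level
# positions only inside the scheduled bout windows, which keeps a 40-day,
# multi-fly cohort tractable; between windows the position evolves at
# episode granularity.

#' @importFrom data.table data.table rbindlist setattr := .N .SD
#' @include AllClasses.R simulate.R classify.R
NULL

#' @rdname generateCohort
#' @export
setClass("FlyCohort",
  representation(frames = "data.frame", manifest = "data.frame",
                 exp = "ExperimentConfig", geometry = "CageGeometry",
                 sim = "SimConfig")
)

setMethod("show", "FlyCohort", function(object) {
  m <- object@manifest
  cat(sprintf("FlyCohort: %d flies, %d frames in %d bouts; %d deaths, %d censored\n",
              nrow(m), nrow(object@frames),
              length(unique(object@frames$boutKey)),
              sum(!is.na(m$deathDay)), sum(is.na(m$deathDay))))
})

#' @param cohort A `FlyCohort`.
#' @rdname generateCohort
#' @export
cohortManifest <- function(cohort) cohort@manifest

#' @param flyId Fly identifier.
#' @rdname generateCohort
#' @details `flyTimeline()` extracts one fly's frames as a plain time-ordered
#'   data.frame (`t`, `x`, `y`, `z`, `truth`, `label`, `boutKey`), the input
#'   expected by the summary operations.
#' @export
flyTimeline <- function(cohort, flyId) {
  fr <- cohort@frames[cohort@frames$flyId == flyId, , drop = FALSE]
  fr[order(fr$t), , drop = FALSE]
}

#' Generate a synthetic lifetime cohort
#'
#' Simulates `nFlies` individually caged flies over `days` days under the
#' round-robin acquisition schedule: each fly's behavioral episode timeline
#' is generated for its whole life, bout windows are sampled at the
#' configured rate, and exact positions are realized inside those windows.
#' Flies whose sampled death day falls inside the horizon stop producing
#' bouts at death; later flies are censored in the manifest.
#'
#' @param nFlies Number of flies (one per cage, recycling over cages).
#' @param days Experiment horizon in days.
#' @param sim A [simConfig()]; per-fly seeds are derived deterministically
#'   from `seed`.
#' @param exp An [experimentConfig()].
#' @param geometry A [cageGeometry()].
#' @param seed Master integer seed.
#' @param tags Optional per-fly condition tags (recycled), stored in the
#'   manifest.
#' @param outDir Optional directory: one sub-directory per fly with daily
#'   bout-log TSVs (via [writeBoutLog()]) plus ground-truth label files and
#'   a cohort manifest CSV. Refuses a non-empty directory unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing non-empty `outDir`.
#' @return A `FlyCohort`. Frame columns: `flyId`, `cage`, `boutKey`,
#'   `startS`, `t` (absolute seconds), `x`, `y`, `z`, `truth` (ground-truth
#'   label), `label` (`NA` until [classifyCohort()]).
#' @examples
#' co <- generateCohort(nFlies = 1, days = 0.05, seed = 1)
#' cohortManifest(co)
#' @export
generateCohort <- function(nFlies, days, sim = simConfig(),
                           exp = experimentConfig(), geometry = cageGeometry(),
                           seed = 1L, tags = "default", outDir = NULL,
                           overwrite = FALSE) {
  stopifnot(nFlies >= 1)
  horizonS <- days * 86400
  startHour <- as.POSIXlt(exp@start)$hour
  sched <- scheduleBouts(exp, horizonS)
  tags <- rep_len(tags, nFlies)
  if (!is.null(outDir)) {
    if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite)
      stop(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                   outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  }
  nFrames <- round(exp@rateHz * exp@boutDurationS)
  perFly <- vector("list", nFlies)
  manifest <- vector("list", nFlies)
  for (i in seq_len(nFlies)) {
    set.seed(.deriveSeed(seed, i))
    flyId <- sprintf("fly%02d", i)
    cage <- (i - 1L) %% exp@cages + 1L
    deathS <- if (is.finite(sim@lifespanMeanlog)) {
      ds <- stats::rlnorm(1, sim@lifespanMeanlog, sim@lifespanSdlog) * 86400
      if (ds < horizonS) ds else NA_real_
    } else NA_real_
    tl <- .episodeTimeline(sim, geometry, horizonS, startHour, 1L, deathS)
    deathTime <- attr(tl, "deathTime")
    starts <- sched$startS[sched$cage == cage]
    if (!is.na(deathTime)) starts <- starts[starts < deathTime]
    boutFrames <- vector("list", length(starts))
    for (b in seq_along(starts)) {
      instants <- starts[b] + (seq_len(nFrames) - 1L) / exp@rateHz
      grid <- round(instants / sim@stepS) * sim@stepS
      r <- .realizeInstants(tl, grid, sim, geometry)
      boutFrames[[b]] <- data.table(
        flyId = flyId, cage = cage,
        boutKey = sprintf("%s_b%05d", flyId, b), startS = starts[b],
        t = instants, x = r$pos[, 1], y = r$pos[, 2], z = r$pos[, 3],
        truth = r$state, label = NA_character_)
    }
    perFly[[i]] <- rbindlist(boutFrames)
    manifest[[i]] <- data.frame(
      flyId = flyId, cage = cage, tag = tags[i],
      deathDay = if (is.na(deathTime)) NA_real_ else deathTime / 86400,
      horizonDays = days)
  }
  frames <- as.data.frame(rbindlist(perFly))
  manifest <- do.call(rbind, manifest)
  cohort <- new("FlyCohort", frames = frames, manifest = manifest, exp = exp,
                geometry = geometry, sim = sim)
  if (!is.null(outDir)) .writeCohortLogs(cohort, outDir)
  cohort
}

.writeCohortLogs <- function(cohort, outDir) {
  exp <- cohort@exp
  fr <- data.table::as.data.table(cohort@frames)
  for (fly in unique(fr$flyId)) {
    flyDir <- file.path(outDir, fly)
    dir.create(flyDir, recursive = TRUE, showWarnings = FALSE)
    sub <- fr[fr$flyId == fly]
    sub[, day := floor(startS / 86400) + 1L]
    for (d in unique(sub$day)) {
      con <- file(file.path(flyDir, sprintf("day%03d.tsv", d)), "w")
      truthCon <- file(file.path(flyDir, sprintf("day%03d_truth.tsv", d)), "w")
      dd <- sub[sub$day == d]
      for (bk in unique(dd$boutKey)) {
        bb <- dd[dd$boutKey == bk]
        b <- bout(fly, as.character(bb$cage[1]), bb$startS[1], exp@rateHz,
                  exp@boutDurationS,
                  data.frame(t = bb$t - bb$startS[1], x = bb$x, y = bb$y,
                             z = bb$z, label = bb$label),
                  cohort@geometry)
        writeBoutLog(b, con, expStart = exp@start)
        writeLines(paste(c(bk, behaviorCodes()[bb$truth]), collapse = "\t"),
                   truthCon)
      }
      close(con); close(truthCon)
    }
  }
  utils::write.csv(cohort@manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(outDir)
}

#' Classify every bout of a cohort
#'
#' Runs the rule-based classifier ([classifyBout()]'s vectorized core) on
#' each bout of the cohort and fills the `label` column of its frame table.
#'
#' @param cohort A [generateCohort()] result.
#' @param cfg A [classifierConfig()].
#' @return The cohort with classified frames.
#' @export
classifyCohort <- function(cohort, cfg = classifierConfig()) {
  fr <- data.table::as.data.table(cohort@frames)
  geom <- cohort@geometry
  fr[, label := .classifyFrames(cbind(x, y, z), cfg, geom), by = boutKey]
  cohort@frames <- as.data.frame(fr)
  cohort
}

#' Per-fly death detection over a classified cohort
#'
#' Applies [detectDeath()] to every fly's classified timeline.
#'
#' @param cohort A classified cohort.
#' @param cfg A [classifierConfig()].
#' @return data.frame with `flyId`, `deathTimeS`, `deathDay` (`NA` when no
#'   qualifying resting span exists).
#' @export
cohortDeaths <- function(cohort, cfg = classifierConfig()) {
  flies <- unique(cohort@frames$flyId)
  res <- lapply(flies, function(f) {
    tl <- flyTimeline(cohort, f)
    d <- detectDeath(tl, cfg)
    data.frame(flyId = f, deathTimeS = d$onsetS,
               deathDay = if (d$dead) d$onsetS / 86400 else NA_real_)
  })
  do.call(rbind, res)
}

#' Simulate labeled validation bouts and measure classifier recall
#'
#' `simulateLabeledBouts()` draws independent single-bout trajectories under
#' peak-activity conditions (peak hour, peak age, so that all behaviors are
#' expressed), samples each at the acquisition rate and retains the
#' ground-truth labels. `classifierRecall()` classifies those bouts and
#' returns per-behavior recall (fraction of ground-truth frames of each
#' behavior recovered by the classifier).
#'
#' @param nBouts Number of independent bouts.
#' @param seed Master seed; per-bout seeds are derived from it.
#' @param sim,exp,geometry,cfg Configuration objects.
#' @return `simulateLabeledBouts()`: list of `(bout, truth)` pairs.
#'   `classifierRecall()`: named numeric vector of per-behavior recall over
#'   the behaviors present in the ground truth.
#' @examples
#' classifierRecall(nBouts = 2, seed = 1)
#' @export
simulateLabeledBouts <- function(nBouts, seed = 42L, sim = simConfig(),
                                 exp = experimentConfig(),
                                 geometry = cageGeometry()) {
  lapply(seq_len(nBouts), function(i) {
    tr <- simulateLifetime(sim, geometry, horizonS = exp@boutDurationS + sim@stepS,
                           seed = .deriveSeed(seed, i),
                           startHour = 18, startDay = round(sim@agePeakDay))
    sampleBout(tr, 0, exp, flyId = sprintf("vb%03d", i), cageId = "c1")
  })
}

#' @rdname simulateLabeledBouts
#' @export
classifierRecall <- function(nBouts = 50, seed = 42L, sim = simConfig(),
                             exp = experimentConfig(),
                             geometry = cageGeometry(),
                             cfg = classifierConfig()) {
  bouts <- simulateLabeledBouts(nBouts, seed, sim, exp, geometry)
  truth <- unlist(lapply(bouts, `[[`, "truth"))
  pred <- unlist(lapply(bouts, function(b)
    ethogramLabels(classifyBout(b$bout, cfg, geometry))))
  present <- intersect(behaviorLabels(), unique(truth))
  vapply(present, function(lv) mean(pred[truth == lv] == lv), numeric(1))
}
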