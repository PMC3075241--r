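# Rule-based six-behavior classifier.
#
# Stage 1 labels each inter-frame transition from its 3D displacement:
# <= deltaRest is resting, >= deltaFly is flying, anything between is left
# pending. Stage 2 partitions frames into tumbling windows of windowN frames
# aligned to the bout start and adjudicates every pending transition in a
# window by the window's net (first-to-last) displacement: <= deltaWalk means
# micro-movement, otherwise walking. Stage 3 relabels maximal resting runs
# that sit wholly inside a station disk and are long enough as feeding or
# drinking. A transition's label goes to its later frame; frame 1 inherits
# the first transition's label. Ties are frozen as <= for resting and the
# walking window, >= for flying.

#' Consecutive-frame displacements of a bout
#'
#' Euclidean distance (mm) between each pair of consecutive 3D positions.
#'
#' @param b A [bout()] with at least two frames.
#' @return Numeric vector of length `nFrames(b) - 1`.
#' @examples
#' b <- makeStationaryBout(5)
#' pairDisplacements(b)
#' @export
pairDisplacements <- function(b) {
  pos <- framePositions(b)
  if (nrow(pos) < 2) stop("validation error: need at least 2 frames")
  sqrt(rowSums(diff(pos)^2))
}

# Vectorized core shared by classifyBout() and the cohort pipeline.
# pos: n x 3 matrix; returns a character label per frame.
.classifyFrames <- function(pos, cfg, geom) {
  n <- nrow(pos)
  d <- sqrt(rowSums(diff(pos)^2))            # transition i: frame i -> i+1
  trans <- rep(NA_character_, n - 1L)
  trans[d <= cfg@deltaRest] <- "resting"
  trans[d >= cfg@deltaFly] <- "flying"

  lab <- c(trans[1L], trans)                 # frame 1 inherits transition 1
  pending <- is.na(lab)
  if (any(pending)) {
    win <- (seq_len(n) - 1L) %/% cfg@windowN
    nw <- max(win) + 1L
    first <- (seq_len(nw) - 1L) * cfg@windowN + 1L
    last <- pmin(first + cfg@windowN - 1L, n)
    net <- sqrt(rowSums((pos[last, , drop = FALSE] -
                           pos[first, , drop = FALSE])^2))
    winLab <- ifelse(net <= cfg@deltaWalk, "micro_movement", "walking")
    lab[pending] <- winLab[win[pending] + 1L]
  }

  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values == "resting" & runs$lengths >= cfg@feedMinPoints)) {
    idx <- starts[r]:ends[r]
    p <- pos[idx, , drop = FALSE]
    if (all(sqrt(colSums((t(p) - geom@foodCenter)^2)) <= cfg@feedRadius))
      lab[idx] <- "feeding"
    else if (all(sqrt(colSums((t(p) - geom@waterCenter)^2)) <= cfg@drinkRadius))
      lab[idx] <- "drinking"
  }
  lab
}

#' Classify a bout into a per-frame ethogram
#'
#' Applies the distance-threshold rules to every frame of a bout, yielding
#' one of the six behaviors per frame.
#'
#' @param b A [bout()] with at least two frames.
#' @param cfg A [classifierConfig()].
#' @param geometry Cage geometry giving the station positions; defaults to
#'   the bout's own geometry.
#' @return An `Ethogram`.
#' @examples
#' classifyBout(makeStationaryBout(10))
#' @export
classifyBout <- function(b, cfg = classifierConfig(), geometry = b@geometry) {
  validObject(b)
  validObject(cfg)
  pos <- framePositions(b)
  if (nrow(pos) < 2) stop("validation error: need at least 2 frames")
  new("Ethogram", labels = .classifyFrames(pos, cfg, geometry), boutRef = b)
}

# --- resting-run chaining and the mortality rule ----------------------------

# Chains consecutive resting frames into runs; frames chain when their
# positions agree within deltaRest, which bridges the unobserved gaps between
# bouts of a motionless fly while any movement (or a relocation during a gap)
# breaks the chain. Returns start/end times and indices of each run.
.restingRuns <- function(t, pos, lab, deltaRest) {
  n <- length(t)
  isRest <- lab == "resting"
  if (n == 1L) {
    if (!isRest) return(data.frame())
    return(data.frame(startT = t, endT = t, startI = 1L, endI = 1L))
  }
  d <- sqrt(rowSums(diff(pos)^2))
  chain <- isRest[-n] & isRest[-1L] & d <= deltaRest
  grp <- cumsum(c(TRUE, !chain))
  keep <- which(isRest)
  if (!length(keep)) return(data.frame())
  g <- grp[keep]
  data.frame(startT = tapply(t[keep], g, min),
             endT = tapply(t[keep], g, max),
             startI = as.integer(tapply(keep, g, min)),
             endI = as.integer(tapply(keep, g, max)),
             row.names = NULL)
}

#' Detect death from a classified timeline
#'
#' A fly is flagged dead when it shows a continuous resting span of at least
#' `deathHours` hours. Resting frames chain across the unobserved gaps
#' between bouts when the flanking positions agree within `deltaRest`; any
#' non-resting frame, or a positional jump, breaks the span.
#'
#' @param timeline A time-ordered data.frame for one fly with columns `t`
#'   (absolute seconds), `x`, `y`, `z` (mm) and `label` (classified).
#' @param cfg A [classifierConfig()].
#' @return A list with `dead` (logical) and `onsetS` (start of the earliest
#'   qualifying resting run in seconds, or `NA`).
#' @examples
#' tl <- data.frame(t = seq(0, 6 * 3600, by = 60), x = 75, y = 75, z = 0,
#'                  label = "resting")
#' detectDeath(tl)
#' @export
detectDeath <- function(timeline, cfg = classifierConfig()) {
  if (!nrow(timeline)) stop("validation error: empty timeline")
  if (is.unsorted(timeline$t, strictly = TRUE))
    stop("validation error: timeline must be strictly time-ordered")
  runs <- .restingRuns(timeline$t, as.matrix(timeline[, c("x", "y", "z")]),
                       timeline$label, cfg@deltaRest)
  if (!nrow(runs)) return(list(dead = FALSE, onsetS = NA_real_))
  hit <- runs$endT - runs$startT >= cfg@deathHours * 3600
  if (!any(hit)) return(list(dead = FALSE, onsetS = NA_real_))
  list(dead = TRUE, onsetS = runs$startT[which(hit)[1]])
}
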