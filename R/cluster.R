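# Age-structured behavioral clustering: 10-day age-group behavior profiles,
# Euclidean and optimal-matching dissimilarities, agglomerative dendrograms
# with bootstrap support, Newick export.

#' Per-fly and cohort age-group behavior profiles
#'
#' Splits life into `widthDays`-day intervals and computes each fly's
#' six-behavior frequency vector per interval ([behaviorFrequencies()]),
#' then averages across the flies with data in the interval. Intervals with
#' no data are dropped with a warning.
#'
#' @param cohort A classified [generateCohort()] result, or a 3D array of
#'   per-fly profiles (`fly x interval x behavior`, NA where a fly has no
#'   data) as produced by `perFlyProfiles()`.
#' @param widthDays Age interval width in days (10 in the standard design).
#' @return A matrix of averaged behavior shares, rows named `"0-10"`,
#'   `"10-20"`, ..., columns the six behaviors, with attribute `perFly`
#'   carrying the underlying array and `nFlies` the per-interval counts.
#' @export
ageGroupMatrix <- function(cohort, widthDays = 10) {
  arr <- if (is.array(cohort) && length(dim(cohort)) == 3) cohort
         else perFlyProfiles(cohort, widthDays)
  if (!dim(arr)[1]) stop("validation error: empty cohort")
  .averageProfiles(arr, warnEmpty = TRUE)
}

.averageProfiles <- function(arr, warnEmpty = FALSE) {
  nFlies <- apply(!is.na(arr[, , 1, drop = FALSE]), 2, sum)
  prof <- apply(arr, c(2, 3), mean, na.rm = TRUE)
  keep <- nFlies > 0
  if (warnEmpty && any(!keep))
    warning(sprintf("dropping %d age interval(s) with no data", sum(!keep)))
  m <- prof[keep, , drop = FALSE]
  attr(m, "perFly") <- arr
  attr(m, "nFlies") <- nFlies[keep]
  m
}

#' @rdname ageGroupMatrix
#' @export
perFlyProfiles <- function(cohort, widthDays = 10) {
  flies <- unique(cohort@frames$flyId)
  maxDay <- max(.lifeDay(cohort@frames$t, cohort@exp))
  breaks <- seq(1, maxDay + widthDays, by = widthDays)
  nInt <- length(breaks) - 1L
  labels <- sprintf("%g-%g", breaks[-length(breaks)] - 1, breaks[-1] - 1)
  arr <- array(NA_real_, dim = c(length(flies), nInt, 6),
               dimnames = list(flies, labels, behaviorLabels()))
  for (i in seq_along(flies)) {
    tl <- flyTimeline(cohort, flies[i])
    for (j in seq_len(nInt)) {
      v <- behaviorFrequencies(tl, c(breaks[j], breaks[j + 1]), cohort@exp)
      if (!is.null(v)) arr[i, j, ] <- v
    }
  }
  arr
}

#' Euclidean distance between behavior profiles
#'
#' @param profiles Matrix of profiles (rows = age groups).
#' @return A symmetric `dist`-class object.
#' @export
euclideanDist <- function(profiles) {
  if (nrow(profiles) < 2) stop("validation error: need at least 2 profiles")
  dist(profiles)
}

# --- optimal matching -------------------------------------------------------

#' Optimal-matching distance between two behavior-label sequences
#'
#' Edit distance by dynamic programming with a constant substitution cost
#' and an insertion/deletion cost: the minimum total cost of transforming
#' one categorical sequence into the other. With the classical default
#' costs (substitution 2, indel 1) this is the standard sequence-analysis
#' dissimilarity for state sequences.
#'
#' @param a,b Character vectors of behavior labels (may be empty).
#' @param subCost,indelCost Positive edit costs.
#' @return Non-negative dissimilarity.
#' @examples
#' omDistance(c("R", "R", "W"), c("R", "W", "W"))
#' @export
omDistance <- function(a, b, subCost = 2, indelCost = 1) {
  stopifnot(subCost > 0, indelCost > 0)
  n <- length(a); m <- length(b)
  if (n == 0) return(m * indelCost)
  if (m == 0) return(n * indelCost)
  prev <- (0:m) * indelCost
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i * indelCost
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + if (a[i] == b[j]) 0 else subCost,
                        prev[j + 1] + indelCost,
                        cur[j] + indelCost)
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Pairwise optimal-matching distance matrix
#'
#' @param seqs List of label sequences (e.g. one representative sequence
#'   per age group).
#' @param subCost,indelCost Edit costs, as in [omDistance()].
#' @param normalize Divide each distance by the longer sequence's length
#'   (empty-vs-empty pairs give 0).
#' @return A symmetric `dist`-class object.
#' @export
omDistanceMatrix <- function(seqs, subCost = 2, indelCost = 1,
                             normalize = FALSE) {
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- omDistance(seqs[[i]], seqs[[j]], subCost, indelCost)
    if (normalize) {
      len <- max(length(seqs[[i]]), length(seqs[[j]]))
      d <- if (len > 0) d / len else 0
    }
    m[i, j] <- m[j, i] <- d
  }
  as.dist(m)
}

#' Representative label sequence of an age interval
#'
#' The modal classified label for each clock hour of the interval,
#' concatenated into a 24-long sequence (hours without data are skipped) —
#' the per-group summary fed to the optimal-matching comparison.
#'
#' @param timeline A classified fly timeline (or rbind of several).
#' @param interval `[startDay, endDay)` in days of life.
#' @param exp An [experimentConfig()].
#' @return Character vector of up to 24 labels.
#' @export
representativeSequence <- function(timeline, interval,
                                   exp = experimentConfig()) {
  day <- .lifeDay(timeline$t, exp)
  sel <- day >= interval[1] & day < interval[2] & !is.na(timeline$label)
  if (!any(sel)) return(character())
  hour <- .clockHour(timeline$t[sel], exp)
  lab <- timeline$label[sel]
  out <- vapply(sort(unique(hour)), function(h) {
    tab <- sort(table(lab[hour == h]), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  out
}

# --- linkage trees ----------------------------------------------------------

#' @rdname linkageTree
#' @export
setClass("LinkageTree",
  representation(merge = "matrix", height = "numeric", labels = "character",
                 method = "character", support = "numeric")
)

setValidity("LinkageTree", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1) return("n leaves require n - 1 merges")
  if (length(object@height) != n - 1) return("one height per merge")
  TRUE
})

setMethod("show", "LinkageTree", function(object) {
  cat(sprintf("LinkageTree (%s linkage): %d leaves, heights %.3g .. %.3g%s\n",
              object@method, length(object@labels), min(object@height),
              max(object@height),
              if (all(is.na(object@support))) ""
              else sprintf("; support %.2f .. %.2f",
                           min(object@support, na.rm = TRUE),
                           max(object@support, na.rm = TRUE))))
})

#' Agglomerative clustering of behavior profiles
#'
#' Standard hierarchical clustering (via `stats::hclust`; `"ward"` maps to
#' `"ward.D2"`) wrapped into a `LinkageTree` that carries the merge matrix,
#' heights, leaf labels and optional per-node bootstrap support.
#'
#' @param d A `dist` object or symmetric non-negative matrix.
#' @param method `"average"` (default), `"complete"` or `"ward"`.
#' @return A `LinkageTree`.
#' @examples
#' lt <- linkageTree(dist(matrix(c(0, 0, 1, 1, 10, 10), ncol = 2,
#'                               byrow = TRUE)))
#' cutLinkage(lt)
#' @export
linkageTree <- function(d, method = c("average", "complete", "ward")) {
  method <- match.arg(method)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(d < 0))
      stop("validation error: distance matrix must be symmetric and non-negative")
    d <- as.dist(d)
  }
  hc <- hclust(d, method = if (method == "ward") "ward.D2" else method)
  labs <- if (is.null(hc$labels)) as.character(seq_len(attr(d, "Size")))
          else hc$labels
  new("LinkageTree", merge = hc$merge, height = hc$height, labels = labs,
      method = method, support = rep(NA_real_, nrow(hc$merge)))
}

.asHclust <- function(tree) {
  structure(list(merge = tree@merge, height = tree@height,
                 order = .leafOrder(tree), labels = tree@labels,
                 method = tree@method),
            class = "hclust")
}

.leafOrder <- function(tree) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(tree@merge[node, 1]), rec(tree@merge[node, 2]))
  }
  rec(nrow(tree@merge))
}

# Leaf index sets of every internal node, in merge order.
.nodeLeafSets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    kids <- merge[i, ]
    sets[[i]] <- sort(c(if (kids[1] < 0) -kids[1] else integer(),
                        if (kids[1] > 0) sets[[kids[1]]] else integer(),
                        if (kids[2] < 0) -kids[2] else integer(),
                        if (kids[2] > 0) sets[[kids[2]]] else integer()))
  }
  sets
}

#' Cut a linkage tree into clusters
#'
#' Cuts at the height yielding exactly `k` clusters. When `k` is `NULL` the
#' automatic cut is used: the number of clusters just below the largest gap
#' between consecutive merge heights (`autoK()`).
#'
#' @param tree A [linkageTree()].
#' @param k Number of clusters (`1 <= k <=` leaves), or `NULL` for
#'   automatic.
#' @return Named integer vector of cluster memberships (leaf -> cluster).
#' @export
cutLinkage <- function(tree, k = NULL) {
  n <- length(tree@labels)
  if (is.null(k)) k <- autoK(tree)
  if (k < 1 || k > n) stop("validation error: k out of range")
  cl <- cutree(.asHclust(tree), k = k)
  setNames(as.integer(cl), tree@labels)
}

#' @rdname cutLinkage
#' @details `autoK()` returns `n - i` where `i` is the merge index after
#'   which the merge heights jump the most (the largest gap criterion); for
#'   a 2-leaf tree it returns 2.
#' @export
autoK <- function(tree) {
  h <- tree@height
  if (length(h) < 2) return(min(2L, length(tree@labels)))
  length(tree@labels) - which.max(diff(h))
}

#' Export a linkage tree as Newick text
#'
#' Branch lengths are parent height minus child height (leaves sit at
#' height 0); bootstrap support values, when present, become internal node
#' labels.
#'
#' @param tree A [linkageTree()].
#' @param digits Branch-length precision.
#' @return A single Newick string (terminated by `;`).
#' @examples
#' lt <- linkageTree(dist(c(a = 0, b = 3)))
#' treeToNewick(lt)
#' @export
treeToNewick <- function(tree, digits = 6) {
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node, parentH) {
    if (node < 0)
      return(sprintf("%s:%s", tree@labels[-node], fmt(parentH)))
    h <- tree@height[node]
    sup <- tree@support[node]
    sprintf("(%s,%s)%s:%s",
            rec(tree@merge[node, 1], h), rec(tree@merge[node, 2], h),
            if (is.na(sup)) "" else fmt(sup),
            fmt(parentH - h))
  }
  root <- nrow(tree@merge)
  h <- tree@height[root]
  sup <- tree@support[root]
  sprintf("(%s,%s)%s;", rec(tree@merge[root, 1], h),
          rec(tree@merge[root, 2], h),
          if (is.na(sup)) "" else fmt(sup))
}

#' Bootstrap support for the age-group dendrogram
#'
#' Resamples flies with replacement `B` times, rebuilds the averaged
#' age-group profiles and the linkage tree for each replicate, and reports
#' for every internal node of the reference tree the fraction of replicates
#' in which the node's leaf set reappears intact (monophyly support).
#'
#' @param flyProfiles Per-fly profile array (`fly x interval x behavior`),
#'   e.g. `attr(ageGroupMatrix(cohort), "perFly")` or [perFlyProfiles()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param method Linkage method, as in [linkageTree()].
#' @return The reference `LinkageTree` with its `support` slot filled
#'   (values in `[0, 1]`, one per internal node in merge order).
#' @export
bootstrapSupport <- function(flyProfiles, B = 100, seed = 1L,
                             method = "average") {
  stopifnot(B >= 1)
  nF <- dim(flyProfiles)[1]
  if (nF < 2) warning("degenerate support: cohort of fewer than 2 flies")
  ref <- .averageProfiles(flyProfiles)
  refTree <- linkageTree(euclideanDist(ref), method)
  refSets <- .nodeLeafSets(refTree@merge)
  refKeys <- vapply(refSets, function(s)
    paste(refTree@labels[s], collapse = "|"), character(1))
  counts <- numeric(length(refKeys))
  set.seed(seed)
  for (b in seq_len(B)) {
    arr <- flyProfiles[sample.int(nF, nF, replace = TRUE), , , drop = FALSE]
    prof <- suppressWarnings(.averageProfiles(arr))
    if (nrow(prof) < 2) next
    bt <- linkageTree(euclideanDist(prof), method)
    sets <- .nodeLeafSets(bt@merge)
    keys <- vapply(sets, function(s) paste(bt@labels[s], collapse = "|"),
                   character(1))
    counts <- counts + (refKeys %in% keys)
  }
  refTree@support <- counts / B
  refTree
}

# --- planted archetypes -----------------------------------------------------

#' Synthetic cohort profiles with three planted age-phase archetypes
#'
#' Builds per-fly age-group behavior profiles for a cohort whose behavioral
#' mix changes with life phase, following the canonical ordering of
#' age-structured fly behavior: a mid-life phase with the highest walking
#' and flying shares, a youngest phase intermediate, and an old phase
#' dominated by resting and micro-movement. Daily profiles get Dirichlet
#' sampling noise plus a per-fly random effect, then average into
#' `widthDays`-day groups — the planted-partition fixture for validating
#' the clustering stage.
#'
#' @param nFlies Number of flies.
#' @param seed Integer seed.
#' @param lifespanDays Common lifespan (days); phases split it in three.
#' @param widthDays Age-group width in days.
#' @param concentration Dirichlet concentration of the daily noise.
#' @param flySd Log-scale sd of the per-fly random effect.
#' @return Per-fly profile array (`fly x interval x behavior`) suitable for
#'   [ageGroupMatrix()] and [bootstrapSupport()].
#' @examples
#' arr <- plantedArchetypeCohort(nFlies = 8, seed = 1)
#' prof <- ageGroupMatrix(arr)
#' cutLinkage(linkageTree(euclideanDist(prof)))
#' @export
plantedArchetypeCohort <- function(nFlies = 16, seed = 1L, lifespanDays = 90,
                                   widthDays = 10, concentration = 300,
                                   flySd = 0.08) {
  set.seed(seed)
  mix <- function(active, p) c(1 - active, active * p)
  phases <- rbind(
    young = mix(0.25, c(0.30, 0.40, 0.12, 0.10, 0.08)),
    mid   = mix(0.35, c(0.20, 0.50, 0.22, 0.05, 0.03)),
    old   = mix(0.10, c(0.45, 0.30, 0.05, 0.12, 0.08)))
  colnames(phases) <- behaviorLabels()
  breaks <- seq(0, lifespanDays, by = widthDays)
  nInt <- length(breaks) - 1L
  labels <- sprintf("%g-%g", breaks[-length(breaks)], breaks[-1])
  arr <- array(NA_real_, dim = c(nFlies, nInt, 6),
               dimnames = list(sprintf("fly%02d", seq_len(nFlies)), labels,
                               behaviorLabels()))
  phaseOf <- function(day) {
    idx <- findInterval(day, c(0, lifespanDays / 3, 2 * lifespanDays / 3),
                        rightmost.closed = FALSE)
    rownames(phases)[pmin(idx, 3L)]
  }
  for (i in seq_len(nFlies)) {
    eff <- exp(rnorm(6, sd = flySd))
    for (j in seq_len(nInt)) {
      days <- seq(breaks[j], breaks[j + 1] - 1)
      daily <- sapply(days, function(d) {
        base <- phases[phaseOf(d + 0.5), ] * eff
        base <- base / sum(base)
        g <- stats::rgamma(6, shape = base * concentration)
        g / sum(g)
      })
      arr[i, j, ] <- rowMeans(daily)
    }
  }
  arr
}
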