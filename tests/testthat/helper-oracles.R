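# Independent reference implementations used as oracles. Deliberately
# written as plain element-by-element loops, separate from the package's
# vectorized code paths.

# Straightforward re-implementation of the three-stage behavior rules.
bruteClassify <- function(pos, cfg, geom) {
  n <- nrow(pos)
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  trans <- character(n - 1)
  for (i in 1:(n - 1)) {
    d <- euclid(pos[i, ], pos[i + 1, ])
    trans[i] <- if (d <= cfg@deltaRest) "resting"
                else if (d >= cfg@deltaFly) "flying"
                else "pending"
  }
  lab <- character(n)
  lab[1] <- trans[1]
  for (i in 1:(n - 1)) lab[i + 1] <- trans[i]

  N <- cfg@windowN
  w <- 1
  while ((w - 1) * N < n) {
    a <- (w - 1) * N + 1
    b <- min(w * N, n)
    verdict <- if (euclid(pos[a, ], pos[b, ]) <= cfg@deltaWalk)
      "micro_movement" else "walking"
    for (i in a:b) if (lab[i] == "pending") lab[i] <- verdict
    w <- w + 1
  }

  relabel <- function(lab, center, radius, minPts, newLab) {
    i <- 1
    while (i <= n) {
      if (lab[i] == "resting") {
        j <- i
        while (j < n && lab[j + 1] == "resting") j <- j + 1
        if (j - i + 1 >= minPts) {
          allIn <- TRUE
          for (k in i:j) if (euclid(pos[k, ], center) > radius) allIn <- FALSE
          if (allIn) for (k in i:j) lab[k] <- newLab
        }
        i <- j + 1
      } else i <- i + 1
    }
    lab
  }
  lab <- relabel(lab, geom@foodCenter, cfg@feedRadius, cfg@feedMinPoints,
                 "feeding")
  lab <- relabel(lab, geom@waterCenter, cfg@drinkRadius, cfg@feedMinPoints,
                 "drinking")
  lab
}

# Exhaustive recursion over edit scripts (no DP table) for short sequences.
bruteEditDistance <- function(a, b, subCost = 2, indelCost = 1) {
  if (length(a) == 0) return(length(b) * indelCost)
  if (length(b) == 0) return(length(a) * indelCost)
  keep <- bruteEditDistance(a[-1], b[-1], subCost, indelCost) +
    if (a[1] == b[1]) 0 else subCost
  del <- bruteEditDistance(a[-1], b, subCost, indelCost) + indelCost
  ins <- bruteEditDistance(a, b[-1], subCost, indelCost) + indelCost
  min(keep, del, ins)
}

# A random bout mixing displacement regimes so every classifier branch is
# exercised, including dwells at the stations.
randomTestBout <- function(n = 60, geom = cageGeometry(), seed = NULL,
                           rateHz = 5) {
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- c(runif(1, 0, geom@width), runif(1, 0, geom@depth),
                runif(1, 0, geom@height))
  scales <- c(0.05, 0.5, 2, 4, 15, 30)
  i <- 2
  while (i <= n) {
    runLen <- min(sample(3:12, 1), n - i + 1)
    sc <- sample(scales, 1)
    target <- NULL
    if (runif(1) < 0.25) {          # dwell near a station now and then
      target <- if (runif(1) < 0.5) geom@foodCenter else geom@waterCenter
      pos[i - 1, ] <- pmin(pmax(target + runif(3, -2, 2), 0),
                           c(geom@width, geom@depth, geom@height))
      sc <- 0.05
    }
    for (k in seq_len(runLen)) {
      step <- stats::rnorm(3)
      step <- sc * step / sqrt(sum(step^2))
      pos[i, ] <- pmin(pmax(pos[i - 1, ] + step, 0),
                       c(geom@width, geom@depth, geom@height))
      i <- i + 1
    }
  }
  pos <- round(pos, 3)
  bout("ft", "c1", 0, rateHz, n / rateHz,
       data.frame(t = (seq_len(n) - 1) / rateHz, x = pos[, 1], y = pos[, 2],
                  z = pos[, 3], label = NA_character_),
       geom)
}

# A synthetic classified timeline: frames every `gapS` seconds, resting with
# a fixed position inside [restStartS, restStartS + restDurS], active with a
# drifting position elsewhere.
restRunTimeline <- function(restDurS, restStartS = 3 * 3600, spanS = 12 * 3600,
                            gapS = 60) {
  t <- seq(0, spanS, by = gapS)
  inRest <- t >= restStartS & t <= restStartS + restDurS
  data.frame(t = t,
             x = ifelse(inRest, 75, 20 + (t %% 7) * 5),
             y = 75, z = ifelse(inRest, 0, 50),
             label = ifelse(inRest, "resting", "walking"),
             boutKey = paste0("b", seq_along(t)))
}
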