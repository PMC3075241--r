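test_that("age-group profiles average flies and tag intervals", {
  # hand-built per-fly profile array: 2 flies x 3 intervals
  arr <- array(NA_real_, c(2, 3, 6),
               dimnames = list(c("f1", "f2"), c("0-10", "10-20", "20-30"),
                               behaviorLabels()))
  arr[1, , ] <- rep(c(1, 0, 0, 0, 0, 0), each = 3)
  arr[2, 1:2, ] <- rep(c(0, 1, 0, 0, 0, 0), each = 2)   # fly 2 dead by day 20
  m <- ageGroupMatrix(arr)
  expect_identical(rownames(m), c("0-10", "10-20", "20-30"))
  expect_equal(unname(m[1, ]), c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(unname(m[3, ]), c(1, 0, 0, 0, 0, 0))     # only fly 1 alive
  expect_equal(attr(m, "nFlies"), c("0-10" = 2L, "10-20" = 2L, "20-30" = 1L))

  empty <- arr; empty[2, 3, ] <- NA; empty[1, 3, ] <- NA
  expect_warning(m2 <- ageGroupMatrix(empty), "no data")
  expect_identical(nrow(m2), 2L)
})

test_that("per-fly profiles from a cohort sum to one per interval", {
  co <- classifyCohort(generateCohort(nFlies = 2, days = 0.2, seed = 5))
  arr <- perFlyProfiles(co, widthDays = 1)
  sums <- apply(arr, c(1, 2), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  m <- ageGroupMatrix(co, widthDays = 1)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)))
})

test_that("euclidean profile distances satisfy the metric axioms", {
  p <- rbind(a = c(1, 0, 0, 0, 0, 0), b = c(0, 1, 0, 0, 0, 0))
  d <- euclideanDist(p)
  expect_equal(as.numeric(d), sqrt(2))
  expect_equal(as.numeric(euclideanDist(rbind(p[1, ], p[1, ]))), 0)

  set.seed(31)
  q <- matrix(runif(30), ncol = 6)
  q <- q / rowSums(q)
  dm <- as.matrix(euclideanDist(q))
  expect_equal(dm, t(dm))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  expect_error(euclideanDist(q[1, , drop = FALSE]), "at least 2")
})

test_that("optimal matching equals exhaustive edit enumeration", {
  expect_equal(omDistance(c("R", "R", "W"), c("R", "W", "W")), 2)
  expect_equal(omDistance(character(), c("R", "W", "F")), 3)
  expect_equal(omDistance(c("R", "W"), c("R", "W")), 0)

  # all pairs of sequences of length <= 4 over a two-label alphabet
  seqs <- list(character())
  for (len in 1:4)
    seqs <- c(seqs, asplit(as.matrix(expand.grid(
      rep(list(c("R", "W")), len), stringsAsFactors = FALSE)), 1))
  for (a in seqs) for (b in seqs)
    expect_equal(omDistance(a, b), bruteEditDistance(a, b))

  # random six-label pairs with asymmetric costs
  set.seed(32)
  labs <- behaviorCodes()
  for (i in 1:40) {
    a <- sample(labs, sample(0:6, 1), replace = TRUE)
    b <- sample(labs, sample(0:6, 1), replace = TRUE)
    expect_equal(omDistance(a, b, subCost = 1.5, indelCost = 0.7),
                 bruteEditDistance(a, b, 1.5, 0.7))
  }
})

test_that("optimal matching is a metric and matches the C edit distance", {
  set.seed(33)
  labs <- unname(behaviorCodes())
  rs <- function() sample(labs, sample(0:20, 1), replace = TRUE)
  for (i in 1:30) {
    a <- rs(); b <- rs(); c <- rs()
    dab <- omDistance(a, b); dba <- omDistance(b, a)
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    if (identical(a, b)) expect_equal(dab, 0) else expect_gt(dab, 0)
    expect_lte(dab, omDistance(a, c) + omDistance(c, b) + 1e-12)
    # independent cross-check against utils::adist with matching costs
    expect_equal(dab, drop(utils::adist(
      paste(a, collapse = ""), paste(b, collapse = ""),
      costs = list(insertions = 1, deletions = 1, substitutions = 2))))
  }
})

test_that("pairwise OM matrices agree with the scalar distance", {
  set.seed(34)
  labs <- unname(behaviorCodes())
  seqs <- lapply(1:5, function(i) sample(labs, 8, replace = TRUE))
  dm <- as.matrix(omDistanceMatrix(seqs))
  for (i in 1:5) for (j in 1:5)
    expect_equal(dm[i, j], omDistance(seqs[[i]], seqs[[j]]))

  same <- rep(list(c("R", "W", "F")), 4)
  expect_true(all(as.matrix(omDistanceMatrix(same)) == 0))

  dn <- as.matrix(omDistanceMatrix(seqs, normalize = TRUE))
  expect_true(all(dn >= 0 & dn <= max(2, 2 * 1)))
})

test_that("linkage trees have n-1 monotone merges and honest Newick", {
  lt <- linkageTree(dist(c(a = 0, b = 3)))
  expect_equal(lt@height, 3)
  expect_identical(treeToNewick(lt), "(a:3,b:3);")
  expect_equal(autoK(lt), 2L)

  set.seed(35)
  m <- matrix(runif(48), ncol = 6, dimnames = list(letters[1:8], NULL))
  for (meth in c("average", "complete", "ward")) {
    lt8 <- linkageTree(euclideanDist(m), meth)
    expect_identical(nrow(lt8@merge), 7L)
    expect_true(!is.unsorted(lt8@height))
    phy <- ape::read.tree(text = treeToNewick(lt8))
    expect_identical(ape::Ntip(phy), 8L)
    expect_setequal(phy$tip.label, letters[1:8])
    # total branch length re-derives from the merge heights
    expect_equal(sum(phy$edge.length),
                 sum(2 * lt8@height) - sum(lt8@height[-length(lt8@height)]),
                 tolerance = 1e-4)
  }

  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(linkageTree(bad), "symmetric")
})

test_that("cutting a tree yields k clusters, with the gap rule for auto-k", {
  arr <- plantedArchetypeCohort(nFlies = 8, seed = 41)
  prof <- ageGroupMatrix(arr)
  lt <- linkageTree(euclideanDist(prof))
  expect_identical(unname(cutLinkage(lt, 1)), rep(1L, 9))
  expect_identical(length(unique(cutLinkage(lt, 9))), 9L)
  expect_error(cutLinkage(lt, 0), "out of range")

  cl <- cutLinkage(lt)                       # auto cut
  expect_identical(length(unique(cl)), 3L)
  # phases are contiguous: 0-30 / 30-60 / 60-90
  expect_identical(length(unique(cl[1:3])), 1L)
  expect_identical(length(unique(cl[4:6])), 1L)
  expect_identical(length(unique(cl[7:9])), 1L)
})

test_that("planted three-phase cohorts recover k = 3 in at least 90% of seeds", {
  hits <- sapply(1:20, function(s) {
    prof <- ageGroupMatrix(plantedArchetypeCohort(nFlies = 16, seed = s))
    autoK(linkageTree(euclideanDist(prof)))
  })
  expect_gte(mean(hits == 3L), 0.9)
})

test_that("bootstrap support is reproducible and high for planted clusters", {
  arr <- plantedArchetypeCohort(nFlies = 16, seed = 42)
  bt <- bootstrapSupport(arr, B = 50, seed = 7)
  expect_true(all(bt@support >= 0 & bt@support <= 1))
  bt2 <- bootstrapSupport(arr, B = 50, seed = 7)
  expect_identical(bt@support, bt2@support)

  sets <- ethotracer:::.nodeLeafSets(bt@merge)
  keys <- sapply(sets, function(s) paste(sort(bt@labels[s]), collapse = "|"))
  planted <- c(paste(sort(rownames(ageGroupMatrix(arr))[1:3]), collapse = "|"),
               paste(sort(rownames(ageGroupMatrix(arr))[4:6]), collapse = "|"),
               paste(sort(rownames(ageGroupMatrix(arr))[7:9]), collapse = "|"))
  for (p in planted) {
    idx <- which(keys == p)
    expect_length(idx, 1L)
    expect_gte(bt@support[idx], 0.9)
  }

  # support values appear as internal node labels in Newick output
  expect_match(treeToNewick(bt), "\\)[0-9.]+:")
})

test_that("representative sequences take the hourly modal label", {
  tl <- data.frame(t = c(3600 * 8 + 0:2, 3600 * 9 + 0:2),
                   x = 0, y = 0, z = 0,
                   label = c("walking", "walking", "resting",
                             "flying", "flying", "flying"),
                   boutKey = "b1")
  rs <- representativeSequence(tl, c(1, 2))
  expect_identical(rs, c("walking", "flying"))
  expect_identical(representativeSequence(tl, c(5, 6)), character())
})
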