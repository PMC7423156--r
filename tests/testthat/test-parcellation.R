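# Connectivity-based parcellation and cluster-reliability statistics.

test_that("similarity matrix is a symmetric unit-diagonal Pearson matrix", {
  rows <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 0, 0))
  S <- similarityMatrix(rows)
  expect_equal(diag(S), rep(1, 3))
  expect_identical(S, t(S))
  expect_equal(S[1, 2], -1 / 3)          # hand Pearson of the two unit rows
  expect_equal(S[1, 3], 1)               # identical rows
  # zero-variance row: similarity 0 to all others, diagonal 1
  S0 <- similarityMatrix(rbind(c(1, 1, 1), c(0, 1, 2)))
  expect_equal(S0[1, 2], 0)
  expect_equal(diag(S0), c(1, 1))
  expect_error(similarityMatrix(matrix(1, 1, 4)), "two")
})

test_that("k-means clustering recovers block structure deterministically", {
  d <- c(10L, 10L, 10L)
  vox <- cbind(1:30, 1L, 1L)
  # block-diagonal similarity with 3 blocks of 10
  S <- matrix(0, 30, 30)
  for (b in 0:2) S[b * 10 + 1:10, b * 10 + 1:10] <- 0.9
  diag(S) <- 1
  sol <- clusterRoi(S, 3, seed = 7, voxels = vox, dim = d)
  truth <- rep(1:3, each = 10)
  # brute-force best-permutation label matching
  best <- max(vapply(combinat_perms(3), function(p) mean(p[sol@labels] == truth),
                     numeric(1)))
  expect_equal(best, 1)
  expect_equal(adjustedRand(sol@labels, truth), 1)
  sol2 <- clusterRoi(S, 3, seed = 7, voxels = vox, dim = d)
  expect_identical(sol@labels, sol2@labels)
  solK1 <- clusterRoi(S, 1, seed = 7, voxels = vox, dim = d)
  expect_identical(unique(solK1@labels), 1L)
  expect_error(clusterRoi(S, 31, seed = 1, voxels = vox, dim = d), "exceeds")
})

test_that("cluster-to-tract assignment matches brute-force optimal matching", {
  d <- c(8L, 8L, 8L)
  ref <- array(0L, d)
  ref[1:20] <- 1L; ref[21:40] <- 2L; ref[41:60] <- 3L
  vox <- .voxFromLin(1:60, d)
  # clusters equal to a permutation of the reference labels
  labels <- c(rep(3L, 20), rep(1L, 20), rep(2L, 20))
  sol <- new("ClusterSolution", voxels = vox, labels = labels, k = 3L,
             subjectId = "s", dim = d)
  asn <- assignClustersToTracts(sol, ref)
  expect_identical(unname(asn), c(2L, 3L, 1L))

  # identity case
  solI <- new("ClusterSolution", voxels = vox, labels = c(rep(1L, 20), rep(2L, 20), rep(3L, 20)),
              k = 3L, subjectId = "s", dim = d)
  expect_identical(unname(assignClustersToTracts(solI, ref)), c(1L, 2L, 3L))

  # a cluster with no overlap to any label is unassigned
  ref2 <- ref; ref2[41:60] <- 0L
  asn2 <- assignClustersToTracts(solI, ref2)
  expect_true(is.na(asn2[["3"]]))

  # brute-force oracle on random overlap structures
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    refR <- array(0L, d)
    refR[seq_len(60)] <- sample(0:k, 60, replace = TRUE)
    labsR <- sample(seq_len(k), 60, replace = TRUE)
    while (length(unique(labsR)) < k) labsR <- sample(seq_len(k), 60, replace = TRUE)
    solR <- new("ClusterSolution", voxels = vox, labels = labsR, k = as.integer(k),
                subjectId = "s", dim = d)
    refIds <- sort(unique(refR[refR > 0]))
    if (k > length(refIds) + 1) next
    ov <- matrix(0, k, length(refIds))
    refAt <- refR[1:60]
    for (cl in seq_len(k)) for (j in seq_along(refIds))
      ov[cl, j] <- sum(refAt == refIds[j] & labsR == cl)
    bestTotal <- 0
    for (p in combinat_perms(max(k, length(refIds)))) {
      tot <- 0
      for (cl in seq_len(k)) {
        j <- p[cl]
        if (j <= length(refIds)) tot <- tot + ov[cl, j]
      }
      bestTotal <- max(bestTotal, tot)
    }
    asnR <- assignClustersToTracts(solR, refR)
    implTotal <- sum(vapply(seq_len(k), function(cl) {
      if (is.na(asnR[cl])) 0 else ov[cl, match(asnR[cl], refIds)]
    }, numeric(1)))
    expect_equal(implTotal, bestTotal)
  }
})

test_that("probability maps count subject fractions", {
  d <- c(6L, 6L, 6L)
  mkSol <- function(voxLin, labels) {
    new("ClusterSolution", voxels = .voxFromLin(voxLin, d),
        labels = as.integer(labels), k = as.integer(max(labels)),
        subjectId = "s", dim = d)
  }
  ref <- array(0L, d); ref[1:4] <- 1L
  sols <- list(mkSol(1:4, c(1, 1, 2, 2)), mkSol(1:4, c(1, 2, 2, 1)),
               mkSol(1:4, c(1, 1, 1, 2)), mkSol(1:4, c(1, 1, 2, 2)))
  asns <- list(c(`1` = 1L, `2` = NA), c(`1` = 1L, `2` = NA),
               c(`1` = 1L, `2` = NA), c(`1` = 1L, `2` = NA))
  pm <- probabilityMaps(sols, asns, tractIds = 1L)
  expect_equal(pm[["1"]][1], 1)       # voxel 1 in all subjects' cluster 1
  expect_equal(pm[["1"]][2], 0.75)
  expect_equal(pm[["1"]][3], 0.25)
  expect_true(all(pm[["1"]] %in% c(0, 0.25, 0.5, 0.75, 1)))
  # single subject: binary map
  pm1 <- probabilityMaps(sols[1], asns[1], tractIds = 1L)
  expect_true(all(pm1[["1"]] %in% c(0, 1)))
})

test_that("derived masks are equally sized, disjoint and conflict-resolved", {
  d <- c(6L, 6L, 6L)
  mk <- function(vals) { a <- array(0, d); a[seq_along(vals)] <- vals; a }
  # disjoint supports: top-5 voxels each
  pA <- mk(c(rep(0.9, 6), rep(0, 6)))
  pB <- mk(c(rep(0, 6), rep(0.8, 6)))
  ms <- deriveMasks(list(middle = list(t1 = pA, t2 = pB)), nVoxels = 5)
  expect_equal(sum(ms@masks$t1$middle), 5)
  expect_equal(sum(ms@masks$t2$middle), 5)
  expect_false(any(ms@masks$t1$middle & ms@masks$t2$middle))
  expect_true(all(which(ms@masks$t1$middle) %in% 1:6))
  expect_true(all(which(ms@masks$t2$middle) %in% 7:12))

  # shared top voxel goes to the higher-probability tract
  pC <- mk(c(0.8, 0.7, 0.6, 0.5, 0, 0))
  pD <- mk(c(0.6, 0, 0, 0, 0.9, 0.5))
  ms2 <- deriveMasks(list(middle = list(t1 = pC, t2 = pD)), nVoxels = 2)
  expect_true(ms2@masks$t1$middle[1])   # 0.8 beats 0.6
  expect_false(ms2@masks$t2$middle[1])
  expect_true(ms2@masks$t2$middle[5])

  # property: random probability maps always yield valid mask sets
  set.seed(9)
  for (rep in 1:15) {
    p1 <- array(stats::runif(prod(d)), d)
    p2 <- array(stats::runif(prod(d)), d)
    p3 <- array(stats::runif(prod(d)), d)
    msR <- deriveMasks(list(anterior = list(a = p1, b = p2, c = p3),
                            middle = list(a = p2, b = p3, c = p1)), nVoxels = 7)
    expect_true(validObject(msR))
  }
  # insufficient voxels raise a named error
  tiny <- mk(c(0.5, 0.5))
  expect_error(deriveMasks(list(middle = list(t1 = tiny)), nVoxels = 5),
               "t1.*middle")
})

test_that("dice and its permutation null behave as set arithmetic", {
  d <- c(5L, 5L, 5L)
  a <- array(FALSE, d); a[1:4] <- TRUE
  b <- array(FALSE, d); b[3:6] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)              # 2*2 / (4+4)
  expect_equal(dice(a, b), dice(b, a))       # symmetry
  expect_error(dice(array(FALSE, d), array(FALSE, d)), "empty")

  # observed dice of identical solutions exceeds the permutation-null maximum
  vox <- .voxFromLin(1:40, d)
  labs <- rep(1:2, each = 20)
  sol <- new("ClusterSolution", voxels = vox, labels = labs, k = 2L,
             subjectId = "s", dim = d)
  dp <- dicePermutationNull(sol, sol, nPerm = 1000, seed = 5)
  expect_equal(unname(dp$observed), c(1, 1))
  expect_gt(min(dp$observed), dp$nullRange[2])
})

test_that("hierarchy index detects nesting and respects its permutation null", {
  d <- c(6L, 6L, 6L)
  vox <- .voxFromLin(1:60, d)
  labK <- rep(1:3, each = 20)
  labK1 <- c(rep(1L, 20), rep(2L, 20), rep(3L, 10), rep(4L, 10))  # split cluster 3
  solK <- new("ClusterSolution", voxels = vox, labels = labK, k = 3L,
              subjectId = "s", dim = d)
  solK1 <- new("ClusterSolution", voxels = vox, labels = labK1, k = 4L,
               subjectId = "s", dim = d)
  hi <- hierarchyIndex(solK, solK1)
  expect_equal(hi$index, 1)

  # invariance under relabeling of either solution
  relab <- c(2L, 3L, 1L)
  solKr <- new("ClusterSolution", voxels = vox, labels = relab[labK], k = 3L,
               subjectId = "s", dim = d)
  expect_equal(hierarchyIndex(solKr, solK1)$index, 1)

  # random relabeling falls inside its own permutation-null range
  set.seed(11)
  labR <- sample(labK1)
  solR <- new("ClusterSolution", voxels = vox, labels = labR, k = 4L,
              subjectId = "s", dim = d)
  hr <- hierarchyIndex(solK, solR, nPerm = 1000, seed = 3)
  expect_gte(hr$index, hr$nullRange[1])
  expect_lte(hr$index, hr$nullRange[2])
  expect_true(hr$index >= 0 && hr$index <= 1)
})

test_that("correspondence percentage and transition flows count voxels", {
  d <- c(5L, 5L, 5L)
  p <- array(FALSE, d); p[1:6] <- TRUE
  cu <- array(FALSE, d); cu[3:8] <- TRUE
  expect_equal(correspondencePercentage(p, cu), 50)   # |int|=4, |uni|=8
  expect_equal(correspondencePercentage(p, p), 100)
  q <- array(FALSE, d); q[10:12] <- TRUE
  expect_equal(correspondencePercentage(p, q), 0)
  expect_equal(correspondencePercentage(p, cu), correspondencePercentage(cu, p))

  vox <- .voxFromLin(1:10, d)
  solK <- new("ClusterSolution", voxels = vox, labels = rep(1L, 10), k = 1L,
              subjectId = "s", dim = d)
  solK1 <- new("ClusterSolution", voxels = vox, labels = c(rep(1L, 7), rep(2L, 3)),
               k = 2L, subjectId = "s", dim = d)
  fl <- clusterTransition(solK, solK1)
  expect_equal(unname(fl[1, ]), c(70, 30))
  expect_equal(unname(rowSums(fl)), 100, tolerance = 1e-9)
})

test_that("end-to-end parcellation recovers bundle membership", {
  ph <- phantomA()
  roi <- roiSpec(19L, ph@bundleLabels > 0)
  conn <- roiConnectivityMatrix(roi, ph@field,
    trackingParams(nSamples = 100, maxSteps = 200, seed = 7), ph@gmMask)
  expect_equal(nrow(conn), nrow(roiVoxels(roi)))
  # rows of voxels in the same zero-dispersion-free bundle correlate strongly
  sim <- similarityMatrix(conn)
  vox <- roiVoxels(roi)
  truth <- ph@bundleLabels[cbind(vox[, 1], vox[, 2], vox[, 3])]
  sameBundle <- outer(truth, truth, `==`)
  expect_gt(mean(sim[sameBundle & upper.tri(sim)]),
            mean(sim[!sameBundle & upper.tri(sim)]))

  # rows of voxels sharing a bundle are far more parallel than rows of
  # voxels in different bundles (the premise of the clustering step)
  cosine <- function(i, j) {
    ri <- as.vector(conn[i, ]); rj <- as.vector(conn[j, ])
    sum(ri * rj) / sqrt(sum(ri^2) * sum(rj^2))
  }
  sameIdx <- which(sameBundle & upper.tri(sameBundle), arr.ind = TRUE)[1:20, ]
  diffIdx <- which(!sameBundle & upper.tri(sameBundle), arr.ind = TRUE)[1:20, ]
  cosSame <- mean(vapply(1:20, function(r) cosine(sameIdx[r, 1], sameIdx[r, 2]), numeric(1)))
  cosDiff <- mean(vapply(1:20, function(r) cosine(diffIdx[r, 1], diffIdx[r, 2]), numeric(1)))
  expect_gt(cosSame, 3 * max(cosDiff, 0.01))
  sol <- clusterRoi(sim, 3, seed = 1, voxels = vox, dim = ph@field@dim)
  expect_gte(adjustedRand(sol@labels, truth), 0.9)
  # assignment recovers the true tract identities
  asn <- assignClustersToTracts(sol, ph@bundleLabels)
  expect_identical(sort(unname(asn)), 1:3)
})
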