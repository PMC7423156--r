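# Connectivity-based parcellation of white-matter ROI voxels, mask
# derivation for tract protocols, and the cluster-reliability statistics
# (Dice and hierarchy index against permutation nulls, correspondence
# percentage, cluster-transition flows).

#' Coronal-analogue ROI specification
#'
#' A slab of consecutive slices along the phantom's y axis (the
#' anteroposterior analogue), restricted to an include mask (tract-bearing
#' white matter) minus optional exclusion masks.
#'
#' @slot axisPosition integer(1) central slice index.
#' @slot nSlices integer(1) number of consecutive slices (default 3).
#' @slot includeMask logical volume.
#' @slot excludeMasks list of logical volumes.
#' @export
setClass("RoiSpec", representation(
  axisPosition = "integer", nSlices = "integer", includeMask = "array",
  excludeMasks = "list"
), validity = function(object) {
  if (object@nSlices < 1L) "nSlices must be >= 1" else TRUE
})

#' @rdname RoiSpec-class
#' @param axisPosition central slice index along y.
#' @param includeMask logical volume restricting the ROI.
#' @param nSlices number of consecutive slices.
#' @param excludeMasks list of logical volumes removed from the ROI.
#' @return `roiSpec()` returns a [RoiSpec-class]; `roiMask()` its logical
#'   volume; `roiVoxels()` the ROI voxel coordinates in ascending linear
#'   order.
#' @export
roiSpec <- function(axisPosition, includeMask, nSlices = 3L, excludeMasks = list()) {
  obj <- new("RoiSpec", axisPosition = as.integer(axisPosition),
             nSlices = as.integer(nSlices), includeMask = includeMask,
             excludeMasks = excludeMasks)
  if (!any(roiMask(obj))) .stopf("ROI is empty")
  obj
}

#' @rdname RoiSpec-class
#' @param roi a [RoiSpec-class].
#' @export
roiMask <- function(roi) {
  d <- dim(roi@includeMask)
  half <- (roi@nSlices - 1L) %/% 2L
  ys <- (roi@axisPosition - half):(roi@axisPosition - half + roi@nSlices - 1L)
  ys <- ys[ys >= 1L & ys <= d[2L]]
  m <- array(FALSE, d)
  m[, ys, ] <- roi@includeMask[, ys, ]
  for (e in roi@excludeMasks) m <- m & !e
  m
}

#' @rdname RoiSpec-class
#' @export
roiVoxels <- function(roi) {
  m <- roiMask(roi)
  .voxCoord(sort(which(as.vector(m))), dim(m))
}

#' ROI-to-brain connectivity matrix
#'
#' Runs unconstrained tractography (no waypoints or exclusions, termination
#' at gray matter) seeded at every ROI voxel and returns the matrix of
#' binary-per-streamline visitation counts: one row per ROI voxel (ascending
#' linear index), one column per brain voxel.
#'
#' @param roi a [RoiSpec-class].
#' @param field an [OrientationField-class].
#' @param params a [TrackingParams-class].
#' @param terminationMask logical volume (typically the gray-matter mask).
#' @return Sparse `nROI x nvox` [Matrix::Matrix] with `rownames` the ROI
#'   voxel linear indices.
#' @export
roiConnectivityMatrix <- function(roi, field, params, terminationMask = NULL) {
  m <- roiMask(roi)
  if (!any(m)) .stopf("ROI is empty")
  lay <- .seedLayout(m, params, field@dim)
  N <- nrow(lay$starts)
  streamSeeds <- NULL
  if (params@mode == "probabilistic") {
    set.seed(params@seed)
    streamSeeds <- sample.int(2147483646L, N)
  }
  res <- .trackCore(field, lay$starts, lay$signs, params,
                    terminationMask = terminationMask,
                    jitterStart = TRUE, streamSeeds = streamSeeds)
  seedIdx <- sort(unique(lay$source))
  rowOf <- match(lay$source, seedIdx)
  conn <- Matrix::sparseMatrix(
    i = rowOf[res$visits$stream], j = res$visits$vox, x = 1,
    dims = c(length(seedIdx), prod(field@dim)))
  rownames(conn) <- seedIdx
  conn
}

#' Similarity matrix of connectivity profiles
#'
#' Entry (i, j) is the Pearson correlation of connectivity rows i and j.
#' The diagonal is 1 and the matrix exactly symmetric; rows with zero
#' variance get similarity 0 to all others.
#'
#' @param conn numeric or sparse matrix, >= 2 rows.
#' @return Dense symmetric `n x n` matrix.
#' @export
similarityMatrix <- function(conn) {
  if (nrow(conn) < 2L) .stopf("need at least two connectivity rows")
  X <- as.matrix(conn)
  suppressWarnings(S <- stats::cor(t(X)))
  S[is.na(S)] <- 0
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' k-means clustering of ROI voxels by connectivity similarity
#'
#' Clusters the rows of the similarity matrix (each voxel represented by its
#' similarity profile) with seeded multi-restart k-means, then relabels the
#' clusters canonically by descending size, ties broken by the lowest member
#' voxel index.
#'
#' @param similarity `n x n` similarity matrix.
#' @param k cluster count, `1 <= k <= n`.
#' @param seed RNG seed.
#' @param voxels `n x 3` ROI voxel coordinates (rows of `similarity`).
#' @param dim integer(3) grid shape.
#' @param subjectId identifier stored in the solution.
#' @param nstart k-means restarts.
#' @return A [ClusterSolution-class].
#' @export
clusterRoi <- function(similarity, k, seed, voxels, dim,
                       subjectId = "subject", nstart = 50L) {
  n <- nrow(similarity)
  if (k > n) .stopf("k (%d) exceeds the number of ROI voxels (%d)", k, n)
  if (k == 1L) {
    labels <- rep(1L, n)
  } else {
    set.seed(seed)
    km <- stats::kmeans(similarity, centers = k, nstart = nstart, iter.max = 100L)
    labels <- as.integer(km$cluster)
  }
  # canonical relabeling: descending cluster size, then lowest voxel index
  sizes <- tabulate(labels, k)
  firstIdx <- vapply(seq_len(k), function(cl) min(which(labels == cl)), integer(1))
  ord <- order(-sizes, firstIdx)
  relab <- integer(k); relab[ord] <- seq_len(k)
  new("ClusterSolution", voxels = matrix(as.integer(voxels), ncol = 3L),
      labels = relab[labels], k = as.integer(k),
      subjectId = as.character(subjectId), dim = as.integer(dim))
}

# Hungarian algorithm (shortest augmenting path with potentials) for a
# square cost matrix; returns the column assigned to each row (minimizing).
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)  # p[j+1]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Assign clusters to reference tracts
#'
#' One-to-one assignment of clusters to reference bundle labels maximizing
#' total cluster-by-label voxel overlap (Hungarian method); ties broken in
#' favor of the lowest tract id.  A cluster overlapping no label maps to
#' `"unassigned"`.
#'
#' @param solution a [ClusterSolution-class].
#' @param reference integer label volume (0 = background).
#' @return Named integer vector: for each cluster (names `"1"..k`) the
#'   assigned reference label id, or `NA` for unassigned.
#' @export
assignClustersToTracts <- function(solution, reference) {
  k <- solution@k
  refIds <- sort(unique(reference[reference > 0L]))
  nt <- length(refIds)
  if (k > nt + 1L)
    .stopf("more clusters (%d) than reference labels (%d) + 1 unassigned slot", k, nt)
  refAt <- reference[.linIdx(solution@voxels, solution@dim)]
  overlap <- matrix(0, k, nt)
  for (cl in seq_len(k)) {
    tab <- tabulate(refAt[solution@labels == cl], nbins = max(refIds))
    overlap[cl, ] <- tab[refIds]
  }
  # pad to square with zero-profit unassigned slots
  n <- max(k, nt)
  profit <- matrix(0, n, n)
  profit[seq_len(k), seq_len(nt)] <- overlap
  # tiny preference for lower tract ids on ties
  tie <- matrix(0, n, n)
  tie[, seq_len(nt)] <- matrix((nt - seq_len(nt) + 1L) * 1e-9, n, nt, byrow = TRUE)
  cost <- max(profit) - (profit + tie)
  assign <- .hungarian(cost)
  out <- rep(NA_integer_, k)
  for (cl in seq_len(k)) {
    j <- assign[cl]
    if (j <= nt && overlap[cl, j] > 0) out[cl] <- refIds[j]
  }
  names(out) <- as.character(seq_len(k))
  out
}

#' Cluster-position probability maps across subjects
#'
#' For each tract, the per-voxel fraction of subjects whose assigned cluster
#' for that tract contains the voxel.
#'
#' @param solutions list of [ClusterSolution-class], one per subject.
#' @param assignments list of assignment vectors from
#'   [assignClustersToTracts()], parallel to `solutions`.
#' @param tractIds integer ids of the tracts to map (default: all assigned).
#' @return Named list of probability volumes, one per tract id.
#' @export
probabilityMaps <- function(solutions, assignments, tractIds = NULL) {
  if (!length(solutions)) .stopf("need at least one subject")
  d <- solutions[[1L]]@dim
  if (is.null(tractIds))
    tractIds <- sort(unique(unlist(lapply(assignments, function(a) a[!is.na(a)]))))
  out <- lapply(tractIds, function(tid) {
    acc <- array(0, d)
    for (s in seq_along(solutions)) {
      sol <- solutions[[s]]
      cl <- which(assignments[[s]] == tid)
      if (length(cl)) {
        sel <- sol@voxels[sol@labels %in% cl, , drop = FALSE]
        acc[.linIdx(sel, d)] <- acc[.linIdx(sel, d)] + 1
      }
    }
    acc / length(solutions)
  })
  names(out) <- as.character(tractIds)
  out
}

#' Derive equally sized, disjoint tract masks from probability maps
#'
#' For each tract and position takes the `nVoxels` highest-probability
#' voxels; a voxel claimed by several tracts goes to the tract with the
#' higher probability there (ties to the lowest tract id) and losers move on
#' to their next-best voxel.
#'
#' @param probMaps nested list `probMaps[[position]][[tract]]` of probability
#'   volumes, positions `"anterior"`, `"middle"`, `"posterior"`.
#' @param nVoxels voxels per mask.
#' @return A [TractMaskSet-class] with `masks[[tract]][[position]]`.
#' @export
deriveMasks <- function(probMaps, nVoxels) {
  positions <- names(probMaps)
  tracts <- names(probMaps[[1L]])
  d <- dim(probMaps[[1L]][[1L]])
  masks <- setNames(lapply(tracts, function(t)
    setNames(vector("list", length(positions)), positions)), tracts)
  for (pos in positions) {
    cand <- lapply(tracts, function(tr) {
      p <- as.vector(probMaps[[pos]][[tr]])
      idx <- which(p > 0)
      idx[order(-p[idx], idx)]
    })
    names(cand) <- tracts
    prob <- lapply(tracts, function(tr) as.vector(probMaps[[pos]][[tr]]))
    names(prob) <- tracts
    taken <- setNames(vector("list", length(tracts)), tracts)
    owner <- integer(prod(d))  # 0 free, else tract index
    cursor <- setNames(rep(1L, length(tracts)), tracts)
    need <- setNames(rep(nVoxels, length(tracts)), tracts)
    repeat {
      open <- tracts[need[tracts] > 0L]
      if (!length(open)) break
      progressed <- FALSE
      for (ti in seq_along(tracts)) {
        tr <- tracts[ti]
        while (need[tr] > 0L) {
          if (cursor[tr] > length(cand[[tr]]))
            .stopf("not enough positive voxels for tract '%s' at position '%s'", tr, pos)
          vx <- cand[[tr]][cursor[tr]]
          cursor[tr] <- cursor[tr] + 1L
          ow <- owner[vx]
          if (ow == 0L) {
            owner[vx] <- ti; taken[[tr]] <- c(taken[[tr]], vx)
            need[tr] <- need[tr] - 1L; progressed <- TRUE
          } else {
            # conflict: higher probability wins, then lower tract id
            po <- prob[[tracts[ow]]][vx]; pn <- prob[[tr]][vx]
            if (pn > po || (pn == po && ti < ow)) {
              loser <- tracts[ow]
              taken[[loser]] <- setdiff(taken[[loser]], vx)
              need[loser] <- need[loser] + 1L
              owner[vx] <- ti; taken[[tr]] <- c(taken[[tr]], vx)
              need[tr] <- need[tr] - 1L; progressed <- TRUE
            }
            # else: this tract lost; continue to its next-best voxel
          }
        }
      }
      if (!progressed && any(need > 0L)) {
        bad <- tracts[need > 0L][1L]
        .stopf("not enough positive voxels for tract '%s' at position '%s'", bad, pos)
      }
    }
    for (tr in tracts) {
      m <- array(FALSE, d); m[taken[[tr]]] <- TRUE
      masks[[tr]][[pos]] <- m
    }
  }
  new("TractMaskSet", masks = masks, nVoxelsPerMask = as.integer(nVoxels))
}

#' Dice coefficient between two binary volumes
#'
#' @param a,b logical volumes on the same grid, not both empty.
#' @return `2|a&b| / (|a| + |b|)`.
#' @export
dice <- function(a, b) {
  if (!.sameGrid(a, b)) .stopf("grids differ")
  denom <- sum(a) + sum(b)
  if (denom == 0) .stopf("both masks are empty")
  2 * sum(a & b) / denom
}

# Binary volume of one cluster of a solution.
.clusterMask <- function(sol, cl) {
  m <- array(FALSE, sol@dim)
  m[.linIdx(sol@voxels[sol@labels == cl, , drop = FALSE], sol@dim)] <- TRUE
  m
}

#' Per-cluster Dice with a permutation null
#'
#' Observed Dice between same-label clusters of two solutions on the same
#' ROI, against a null built by randomly permuting the voxel-to-cluster
#' labels of the second solution `nPerm` times.
#'
#' @param solA,solB [ClusterSolution-class] on the same ROI voxels with the
#'   same k.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return List with `observed` (per-cluster Dice), `nullRange`
#'   (min and max over all permutations and clusters) and `null` (the
#'   `nPerm x k` matrix of permuted Dice values).
#' @export
dicePermutationNull <- function(solA, solB, nPerm = 1000L, seed = 1L) {
  if (!identical(solA@voxels, solB@voxels)) .stopf("solutions must share ROI voxels")
  if (nPerm < 1L) .stopf("nPerm must be >= 1")
  k <- solA@k
  obs <- vapply(seq_len(k), function(cl)
    dice(.clusterMask(solA, cl), .clusterMask(solB, cl)), numeric(1))
  set.seed(seed)
  nullMat <- matrix(NA_real_, nPerm, k)
  labB <- solB@labels
  n <- length(labB)
  for (p in seq_len(nPerm)) {
    perm <- labB[sample.int(n)]
    for (cl in seq_len(k)) {
      aCl <- solA@labels == cl
      bCl <- perm == cl
      nullMat[p, cl] <- 2 * sum(aCl & bCl) / (sum(aCl) + sum(bCl))
    }
  }
  list(observed = obs, nullRange = range(nullMat), null = nullMat)
}

#' Hierarchy index between nested cluster solutions
#'
#' Each cluster of the (k+1)-solution is assigned a parent: the k-solution
#' cluster with maximal voxel overlap.  The index is the fraction of ROI
#' voxels whose (k+1)-cluster's parent contains them — 1 for a perfect
#' refinement.  An optional permutation null permutes the (k+1) labels.
#'
#' @param solK,solK1 [ClusterSolution-class] on identical ROI voxels with
#'   `solK1@k == solK@k + 1`.
#' @param nPerm permutations for the null (0 = none).
#' @param seed RNG seed.
#' @return List with `index` and, when `nPerm > 0`, `nullRange` and `null`.
#' @export
hierarchyIndex <- function(solK, solK1, nPerm = 0L, seed = 1L) {
  if (!identical(solK@voxels, solK1@voxels)) .stopf("solutions must share ROI voxels")
  if (solK1@k != solK@k + 1L) .stopf("solK1 must have exactly one more cluster")
  idx <- .hierarchyIndexRaw(solK@labels, solK1@labels, solK@k, solK1@k)
  out <- list(index = idx)
  if (nPerm > 0L) {
    set.seed(seed)
    n <- length(solK1@labels)
    nullVals <- vapply(seq_len(nPerm), function(p)
      .hierarchyIndexRaw(solK@labels, solK1@labels[sample.int(n)],
                         solK@k, solK1@k), numeric(1))
    out$nullRange <- range(nullVals)
    out$null <- nullVals
  }
  out
}

.hierarchyIndexRaw <- function(labK, labK1, k, k1) {
  tab <- table(factor(labK1, levels = seq_len(k1)), factor(labK, levels = seq_len(k)))
  parent <- apply(tab, 1L, which.max)
  mean(labK == parent[labK1])
}

#' Percentage overlap between a parent cluster and a child union
#'
#' @param parent,childUnion logical volumes, not both empty.
#' @return `100 * |intersection| / |union|`.
#' @export
correspondencePercentage <- function(parent, childUnion) {
  if (!.sameGrid(parent, childUnion)) .stopf("grids differ")
  un <- sum(parent | childUnion)
  if (un == 0) .stopf("both masks are empty")
  100 * sum(parent & childUnion) / un
}

#' Cluster-transition flow table
#'
#' Percentage of each parent cluster's voxels allocated to each child
#' cluster when the cluster count increases; rows sum to 100.
#'
#' @param solK,solK1 [ClusterSolution-class] on identical ROI voxels.
#' @return `k x k1` matrix of percentages.
#' @export
clusterTransition <- function(solK, solK1) {
  if (!identical(solK@voxels, solK1@voxels)) .stopf("solutions must share ROI voxels")
  tab <- table(factor(solK@labels, levels = seq_len(solK@k)),
               factor(solK1@labels, levels = seq_len(solK1@k)))
  flow <- 100 * sweep(unclass(tab), 1L, rowSums(tab), `/`)
  dimnames(flow) <- list(parent = seq_len(solK@k), child = seq_len(solK1@k))
  flow
}
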