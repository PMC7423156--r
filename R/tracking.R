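# Streamline tractography over an OrientationField under seed / waypoint /
# exclusion / termination protocols.
#
# Coordinate convention: continuous positions are in voxel units; voxel
# (i, j, k) spans [i-1, i) x [j-1, j) x [k-1, k) and has center (i,j,k)-0.5.
# Orientation lookup and every mask test use the containing voxel (no
# interpolation), so test expectations are exact.  Step length is given in
# mm and converted through the field's voxel size.
#
# Reproducibility protocol (replayed verbatim by the brute-force test
# oracle): in probabilistic mode a master generator seeded with
# `params@seed` draws one substream seed per streamline via
# `sample.int(2147483646L, N)`.  Streamlines are ordered by ascending seed
# voxel linear index, then by sample index within the voxel; sample s gets
# initial sign +1 when odd, -1 when even.  Each streamline then consumes,
# from `set.seed(<its substream seed>)`, exactly three uniforms for the
# start offset within its seed voxel followed by three uniforms per step
# (selection, angle, axis) regardless of voxel type.  Deterministic mode
# consumes no random numbers at all and launches one streamline per initial
# sign from each seed voxel center.

#' Create tracking parameters
#'
#' @param nSamples streamlines per seed voxel (probabilistic mode).
#' @param maxSteps cap on propagation steps.
#' @param stepLength step length in mm.
#' @param curvatureThreshold minimum cosine between successive step
#'   directions; a candidate step turning more sharply stops the streamline.
#' @param mode `"probabilistic"` or `"deterministic"`.
#' @param seed base RNG seed for the run.
#' @return A [TrackingParams-class].
#' @export
trackingParams <- function(nSamples = 10000L, maxSteps = 2000L, stepLength = 0.5,
                           curvatureThreshold = 0.2,
                           mode = c("probabilistic", "deterministic"),
                           seed = 1L) {
  new("TrackingParams", nSamples = as.integer(nSamples),
      maxSteps = as.integer(maxSteps), stepLength = as.numeric(stepLength),
      curvatureThreshold = as.numeric(curvatureThreshold),
      mode = match.arg(mode), seed = as.integer(seed))
}

#' Create a tract protocol
#'
#' @param name tract identifier.
#' @param seedMask logical volume of seed voxels (non-empty).
#' @param waypointMasks list of logical volumes; a streamline is retained if
#'   it crosses at least one of them (OR logic).  Empty list: no retention
#'   constraint.
#' @param exclusionMasks list of logical volumes; contact anywhere (including
#'   the seed step) deletes the streamline.
#' @param terminationMask logical volume; entering it stops the streamline
#'   without deleting it.  `NULL` for none.
#' @param params a [TrackingParams-class].
#' @return A [TractProtocol-class].
#' @export
tractProtocol <- function(name, seedMask, waypointMasks = list(),
                          exclusionMasks = list(), terminationMask = NULL,
                          params = trackingParams()) {
  if (is.null(terminationMask)) terminationMask <- array(FALSE, dim(seedMask))
  new("TractProtocol", name = as.character(name),
      seedMask = seedMask, waypointMasks = waypointMasks,
      exclusionMasks = exclusionMasks, terminationMask = terminationMask,
      params = params)
}

#' Uniform single-orientation field
#'
#' Convenience constructor for tests and examples: every voxel carries the
#' same single orientation with weight 1 (no voxel is isotropic).
#'
#' @param dim integer(3) grid shape.
#' @param direction 3-vector; stored with canonical axial sign.
#' @param voxelSize mm.
#' @param dispersionDeg angular sd for probabilistic re-perturbation.
#' @return An [OrientationField-class].
#' @export
uniformField <- function(dim, direction, voxelSize = 1, dispersionDeg = 0) {
  dim <- as.integer(dim)
  nvox <- prod(dim)
  d <- .canonicalSign(.unitRows(matrix(direction, 1L, 3L)))
  orientations <- array(0, c(nvox, 1L, 3L))
  orientations[, 1L, ] <- matrix(d, nvox, 3L, byrow = TRUE)
  new("OrientationField", dim = dim, voxelSize = as.numeric(voxelSize),
      orientations = orientations, weights = matrix(1, nvox, 1L),
      dispersionDeg = as.numeric(dispersionDeg), isotropic = rep(FALSE, nvox))
}

# Candidate step directions for a set of streamlines (vectorized).
# li: linear voxel indices; prevDir: n x 3 or rows of NA; hasDir: logical;
# signs: initial signs used where !hasDir; u*: per-streamline uniforms.
.candDirections <- function(field, li, prevDir, hasDir, signs, uSel, uA, uB,
                            deterministic) {
  n <- length(li)
  K <- dim(field@orientations)[2L]
  iso <- field@isotropic[li]
  cand <- matrix(NA_real_, n, 3L)

  ni <- which(!iso)
  if (length(ni)) {
    if (K == 1L) {
      k <- rep(1L, length(ni))
    } else {
      w <- field@weights[li[ni], , drop = FALSE]
      if (deterministic) {
        k <- max.col(w, ties.method = "first")
      } else {
        cw <- t(apply(w, 1L, cumsum))
        tgt <- uSel[ni] * cw[, K]
        k <- rep(K, length(ni))
        for (kk in (K - 1L):1L) k[tgt <= cw[, kk]] <- kk
      }
    }
    o <- matrix(0, length(ni), 3L)
    for (kk in unique(k)) {
      rows <- which(k == kk)
      o[rows, ] <- field@orientations[li[ni][rows], kk, , drop = TRUE]
    }
    o <- matrix(o, ncol = 3L)
    if (!deterministic && field@dispersionDeg > 0) {
      theta <- abs(qnorm(.clampU(uA[ni]))) * field@dispersionDeg * pi / 180
      phi <- 2 * pi * uB[ni]
      pb <- .perpBasis(o)
      o <- cos(theta) * o + sin(theta) * (cos(phi) * pb$e1 + sin(phi) * pb$e2)
      o <- .canonicalSign(o)
    }
    cand[ni, ] <- o
  }

  ii <- which(iso)
  if (length(ii)) {
    if (deterministic) {
      # no preferred orientation: continue straight when possible
      cont <- ii[hasDir[ii]]
      cand[cont, ] <- prevDir[cont, , drop = FALSE]
      # rows with no previous direction keep NA (caller stops them)
    } else {
      ct <- 2 * uA[ii] - 1
      st <- sqrt(pmax(0, 1 - ct^2))
      phi <- 2 * pi * uB[ii]
      cand[ii, ] <- .canonicalSign(cbind(st * cos(phi), st * sin(phi), ct))
    }
  }

  # Sign handling: align with the previous direction where there is one,
  # otherwise apply the initial launch sign.
  hd <- which(hasDir & !is.na(cand[, 1L]))
  if (length(hd)) {
    dp <- rowSums(cand[hd, , drop = FALSE] * prevDir[hd, , drop = FALSE])
    fl <- dp < 0
    cand[hd[fl], ] <- -cand[hd[fl], , drop = FALSE]
  }
  nh <- which(!hasDir & !is.na(cand[, 1L]))
  if (length(nh)) cand[nh, ] <- cand[nh, , drop = FALSE] * signs[nh]
  cand
}

#' Sample a propagation direction at one position
#'
#' Probabilistic mode draws one stored orientation weight-proportionally and
#' re-perturbs it by the field's angular dispersion (consuming exactly three
#' uniforms from the current RNG stream); deterministic mode returns the
#' highest-weight orientation unperturbed and consumes none.  The sign is
#' flipped so that the result has non-negative dot product with
#' `previousDir` when one is given.
#'
#' @param field an [OrientationField-class].
#' @param position continuous position in voxel units (inside the grid).
#' @param previousDir unit 3-vector or `NULL`.
#' @param mode `"probabilistic"` or `"deterministic"`.
#' @return Unit 3-vector.
#' @export
sampleOrientation <- function(field, position,
                              previousDir = NULL,
                              mode = c("probabilistic", "deterministic")) {
  mode <- match.arg(mode)
  vox <- .posToVox(matrix(position, 1L, 3L))
  if (!.inGrid(vox, field@dim)) .stopf("position outside the grid")
  li <- .linIdx(vox, field@dim)
  det <- mode == "deterministic"
  u <- if (det) c(0, 0, 0) else runif(3L)
  hasDir <- !is.null(previousDir)
  prev <- if (hasDir) matrix(previousDir, 1L, 3L) else matrix(NA_real_, 1L, 3L)
  d <- .candDirections(field, li, prev, hasDir, signs = 1, uSel = u[1L],
                       uA = u[2L], uB = u[3L], deterministic = det)
  if (anyNA(d)) .stopf("no orientation available at an isotropic voxel in deterministic mode")
  as.numeric(d)
}

# Core lockstep streamline propagator.  starts: N x 3 voxel-unit positions
# (voxel corners when jitterStart, exact starts otherwise); signs: +/-1.
# Returns per-streamline status, waypoint hits, deduplicated (stream, voxel)
# visits, and optionally full polylines.
.trackCore <- function(field, starts, signs, params,
                       waypointMasks = list(), exclusionMasks = list(),
                       terminationMask = NULL, jitterStart = TRUE,
                       streamSeeds = NULL, recordPaths = FALSE,
                       batchSize = 4096L) {
  dimg <- field@dim
  nvox <- prod(dimg)
  N <- nrow(starts)
  det <- params@mode == "deterministic"
  stepVox <- params@stepLength / field@voxelSize
  curv <- params@curvatureThreshold
  W <- length(waypointMasks)
  wp <- lapply(waypointMasks, as.vector)
  ex <- lapply(exclusionMasks, as.vector)
  tm <- if (is.null(terminationMask)) NULL else as.vector(terminationMask)

  status <- character(N)
  wayHit <- matrix(FALSE, N, max(1L, W))
  visStream <- vector("list", 0L)
  visVox <- vector("list", 0L)
  paths <- if (recordPaths) vector("list", N) else NULL

  chunkSteps <- min(params@maxSteps, 400L)

  for (b0 in seq(1L, N, by = batchSize)) {
    batch <- b0:min(N, b0 + batchSize - 1L)
    n <- length(batch)
    ndraw <- 3L + 3L * chunkSteps
    U <- NULL
    chunkBase <- 0L  # steps covered before current chunk
    if (!det) {
      U <- matrix(0, n, ndraw)
      for (m in seq_len(n)) {
        set.seed(streamSeeds[batch[m]])
        U[m, ] <- runif(ndraw)
      }
    }

    pos <- starts[batch, , drop = FALSE]
    if (!det && jitterStart) pos <- pos + U[, 1:3]
    dir <- matrix(NA_real_, n, 3L)
    hasDir <- rep(FALSE, n)
    alive <- rep(TRUE, n)
    st <- rep("", n)
    wh <- matrix(FALSE, n, max(1L, W))
    vs <- vector("list", params@maxSteps + 1L)
    vv <- vector("list", params@maxSteps + 1L)
    if (recordPaths) pp <- lapply(seq_len(n), function(i) list(pos[i, ]))

    # Visit and mask checks at the start voxel.
    v0 <- .posToVox(pos)
    ing <- .inGrid(v0, dimg)
    if (any(!ing)) { st[!ing] <- "exit"; alive[!ing] <- FALSE }
    li0 <- rep(NA_integer_, n)
    li0[ing] <- .linIdx(v0[ing, , drop = FALSE], dimg)
    ok <- which(ing)
    vs[[1L]] <- batch[ok]; vv[[1L]] <- li0[ok]
    for (e in ex) {
      hit <- ok[e[li0[ok]]]
      if (length(hit)) { st[hit] <- "excluded"; alive[hit] <- FALSE }
    }
    if (W) for (wi in seq_len(W)) {
      hit <- ok[wp[[wi]][li0[ok]]]
      wh[hit, wi] <- TRUE
    }
    if (!is.null(tm)) {
      hit <- ok[tm[li0[ok]] & alive[ok]]
      if (length(hit)) { st[hit] <- "terminated"; alive[hit] <- FALSE }
    }

    s <- 0L
    while (any(alive) && s < params@maxSteps) {
      s <- s + 1L
      # extend the pregenerated draw chunk if needed
      if (!det && s > chunkBase + chunkSteps) {
        chunkBase <- chunkBase + chunkSteps
        aset <- which(alive)
        U <- matrix(0, n, 3L * chunkSteps)
        skip <- 3L + 3L * chunkBase
        for (m in aset) {
          set.seed(streamSeeds[batch[m]])
          runif(skip)
          U[m, ] <- runif(3L * chunkSteps)
        }
        # after the first chunk the 3 start draws are part of `skip`
      }
      ai <- which(alive)
      vox <- .posToVox(pos[ai, , drop = FALSE])
      li <- .linIdx(vox, dimg)
      if (det) {
        uS <- uA <- uB <- numeric(length(ai))
      } else {
        off <- if (chunkBase == 0L) 3L + 3L * (s - 1L) else 3L * (s - chunkBase - 1L)
        uS <- U[ai, off + 1L]; uA <- U[ai, off + 2L]; uB <- U[ai, off + 3L]
      }
      cand <- .candDirections(field, li, dir[ai, , drop = FALSE],
                              hasDir[ai], signs[batch[ai]], uS, uA, uB, det)
      # streamlines with no available direction (deterministic isotropic, no prev)
      nodir <- is.na(cand[, 1L])
      if (any(nodir)) {
        rows <- ai[nodir]
        st[rows] <- "no_direction"; alive[rows] <- FALSE
        ai <- ai[!nodir]; cand <- cand[!nodir, , drop = FALSE]
        if (!length(ai)) next
      }
      # curvature stop (skipped on the first step of each streamline)
      chk <- which(hasDir[ai])
      if (length(chk)) {
        dp <- rowSums(cand[chk, , drop = FALSE] * dir[ai[chk], , drop = FALSE])
        bad <- dp < curv
        if (any(bad)) {
          rows <- ai[chk[bad]]
          st[rows] <- "curvature"; alive[rows] <- FALSE
          keep <- !(ai %in% rows)
          cand <- cand[keep, , drop = FALSE]; ai <- ai[keep]
          if (!length(ai)) next
        }
      }
      newpos <- pos[ai, , drop = FALSE] + stepVox * cand
      nv <- .posToVox(newpos)
      inb <- .inGrid(nv, dimg)
      if (any(!inb)) {
        rows <- ai[!inb]
        st[rows] <- "exit"; alive[rows] <- FALSE
      }
      keep <- which(inb)
      if (!length(keep)) next
      rows <- ai[keep]
      liN <- .linIdx(nv[keep, , drop = FALSE], dimg)
      vs[[s + 1L]] <- batch[rows]; vv[[s + 1L]] <- liN
      pos[rows, ] <- newpos[keep, , drop = FALSE]
      dir[rows, ] <- cand[keep, , drop = FALSE]
      hasDir[rows] <- TRUE
      if (recordPaths) for (r in seq_along(rows))
        pp[[rows[r]]][[length(pp[[rows[r]]]) + 1L]] <- pos[rows[r], ]
      for (e in ex) {
        hit <- rows[e[liN]]
        if (length(hit)) { st[hit] <- "excluded"; alive[hit] <- FALSE }
      }
      if (W) for (wi in seq_len(W)) {
        hit <- rows[wp[[wi]][liN]]
        wh[hit, wi] <- TRUE
      }
      if (!is.null(tm)) {
        hit <- rows[tm[liN] & alive[rows]]
        if (length(hit)) { st[hit] <- "terminated"; alive[hit] <- FALSE }
      }
    }
    st[alive] <- "max_steps"
    status[batch] <- st
    wayHit[batch, ] <- wh
    visStream[[length(visStream) + 1L]] <- unlist(vs)
    visVox[[length(visVox) + 1L]] <- unlist(vv)
    if (recordPaths) for (m in seq_len(n))
      paths[[batch[m]]] <- do.call(rbind, pp[[m]])
  }

  stream <- unlist(visStream)
  vox <- unlist(visVox)
  key <- (as.numeric(stream) - 1) * nvox + vox
  dedup <- !duplicated(key)
  list(status = status, wayHit = wayHit,
       visits = list(stream = stream[dedup], vox = vox[dedup]),
       paths = paths)
}

# Seed/sign layout shared by production code and documentation: voxels in
# ascending linear order, samples within voxel, alternating signs.
.seedLayout <- function(seedMask, params, dimg) {
  seedIdx <- sort(which(as.vector(seedMask)))
  if (params@mode == "deterministic") {
    nPer <- 2L
    starts <- .voxCoord(rep(seedIdx, each = nPer), dimg) - 0.5  # voxel centers
    signs <- rep(c(1, -1), length(seedIdx))
  } else {
    nPer <- params@nSamples
    starts <- .voxCoord(rep(seedIdx, each = nPer), dimg) - 1L  # voxel corners
    signs <- rep(rep(c(1, -1), length.out = nPer), length(seedIdx))
  }
  list(starts = matrix(as.numeric(starts), ncol = 3L), signs = signs,
       source = rep(seedIdx, each = nPer))
}

#' Propagate one streamline
#'
#' Euler-steps a single streamline from `start` under a protocol, for
#' inspection and debugging.  In probabilistic mode the draws come from the
#' substream seeded with `seed` (three start-offset uniforms are consumed
#' but unused, then three per step, exactly as in [runTractography()]).
#'
#' @param field an [OrientationField-class].
#' @param start continuous start position in voxel units (inside the seed).
#' @param protocol a [TractProtocol-class].
#' @param initialSign +1 or -1 launch sign.
#' @param seed substream seed (probabilistic mode).
#' @return List with `path` (steps+1 x 3 matrix of voxel-unit positions),
#'   `status`, `waypointsHit` (logical per waypoint mask), `excluded`.
#' @export
propagateStreamline <- function(field, start, protocol, initialSign = 1,
                                seed = 1L) {
  vox <- .posToVox(matrix(start, 1L, 3L))
  if (!.inGrid(vox, field@dim)) .stopf("start position outside the grid")
  res <- .trackCore(field, matrix(start, 1L, 3L), signs = initialSign,
                    params = protocol@params,
                    waypointMasks = protocol@waypointMasks,
                    exclusionMasks = protocol@exclusionMasks,
                    terminationMask = protocol@terminationMask,
                    jitterStart = FALSE, streamSeeds = as.integer(seed),
                    recordPaths = TRUE)
  list(path = res$paths[[1L]], status = res$status[1L],
       waypointsHit = if (length(protocol@waypointMasks))
         res$wayHit[1L, seq_along(protocol@waypointMasks)] else logical(0),
       excluded = res$status[1L] == "excluded")
}

#' Run protocol-constrained tractography
#'
#' Launches `nSamples` streamlines from every seed voxel (uniform random
#' start within the voxel, half of the samples with each initial axial
#' sign), discards streamlines touching any exclusion mask, retains those
#' crossing at least one waypoint (all of them if no waypoints are defined),
#' and accumulates per-voxel visitation counts, each retained streamline
#' counting at most once per voxel.  The normalized map divides counts by
#' the number of retained streamlines.
#'
#' @param protocol a [TractProtocol-class].
#' @param field an [OrientationField-class].
#' @return A [Tractogram-class].
#' @export
runTractography <- function(protocol, field) {
  validObject(protocol)
  params <- protocol@params
  dimg <- field@dim
  lay <- .seedLayout(protocol@seedMask, params, dimg)
  N <- nrow(lay$starts)
  streamSeeds <- NULL
  if (params@mode == "probabilistic") {
    set.seed(params@seed)
    streamSeeds <- sample.int(2147483646L, N)
  }
  res <- .trackCore(field, lay$starts, lay$signs, params,
                    waypointMasks = protocol@waypointMasks,
                    exclusionMasks = protocol@exclusionMasks,
                    terminationMask = protocol@terminationMask,
                    jitterStart = TRUE, streamSeeds = streamSeeds)
  retained <- res$status != "excluded"
  if (length(protocol@waypointMasks))
    retained <- retained & rowSums(res$wayHit[, seq_along(protocol@waypointMasks),
                                              drop = FALSE]) > 0
  nRet <- sum(retained)
  counts <- numeric(prod(dimg))
  if (nRet > 0) {
    keep <- retained[res$visits$stream]
    tab <- tabulate(res$visits$vox[keep], nbins = prod(dimg))
    counts <- as.numeric(tab)
  }
  counts <- array(counts, dimg)
  if (nRet == 0) {
    .warnf("protocol '%s': no streamlines retained", protocol@name)
    normalized <- array(0, dimg)
  } else {
    normalized <- counts / nRet
  }
  new("Tractogram", counts = counts, nGenerated = N, nRetained = as.integer(nRet),
      normalized = normalized, protocolName = protocol@name,
      voxelSize = field@voxelSize)
}

#' Average normalized tractograms voxelwise
#'
#' @param tractograms list of [Tractogram-class] (or numeric volumes) on the
#'   same grid.
#' @return Numeric volume: the arithmetic mean of the normalized maps.
#' @export
averageTractograms <- function(tractograms) {
  if (!length(tractograms)) .stopf("need at least one tractogram")
  vols <- lapply(tractograms, function(t)
    if (is(t, "Tractogram")) t@normalized else t)
  d <- dim(vols[[1L]])
  for (v in vols) if (!identical(dim(v), d)) .stopf("tractogram grids differ")
  Reduce(`+`, vols) / length(vols)
}

#' Downsample a volume by block-mean pooling
#'
#' @param volume numeric 3-D array.
#' @param factor integer >= 1 dividing every grid dimension.
#' @return Volume of shape `dim(volume) / factor`; each output voxel is the
#'   mean of its `factor^3` block.
#' @export
downsampleVolume <- function(volume, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) .stopf("factor must be >= 1")
  d <- dim(volume)
  if (any(d %% factor != 0L)) .stopf("factor must divide every grid dimension")
  if (factor == 1L) return(volume)
  nd <- d %/% factor
  a <- array(volume, c(factor, nd[1L], factor, nd[2L], factor, nd[3L]))
  out <- apply(a, c(2L, 4L, 6L), mean)
  array(out, nd)
}

#' Log-transform and normalize a volume for display
#'
#' Applies `log(1 + v)` and divides by the maximum, mapping the volume into
#' `[0, 1]` while preserving the ordering of voxel values.  An all-zero
#' volume is returned unchanged with a warning.
#'
#' @param volume non-negative numeric volume.
#' @return Volume in `[0, 1]`.
#' @export
logNormalize <- function(volume) {
  if (any(volume < 0)) .stopf("volume must be non-negative")
  v <- log1p(volume)
  m <- max(v)
  if (m == 0) {
    .warnf("all-zero volume: returned unchanged")
    return(volume)
  }
  v / m
}

#' Threshold a display volume
#'
#' @param volume numeric volume.
#' @param t threshold; voxels `>= t` are kept.
#' @return Logical volume.
#' @export
thresholdMap <- function(volume, t) volume >= t

#' Fraction of one tract's voxels overlapped by another
#'
#' @param tractA,tractB logical volumes on the same grid; `tractA` non-empty.
#' @return `|A intersect B| / |A|`.
#' @export
overlapFraction <- function(tractA, tractB) {
  if (!.sameGrid(tractA, tractB)) .stopf("grids differ")
  na <- sum(tractA)
  if (na == 0) .stopf("tractA is empty")
  sum(tractA & tractB) / na
}
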