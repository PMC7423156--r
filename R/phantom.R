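# Synthetic species phantoms: parameterized fiber-orientation fields with
# known bundle ground truth, a gray/white border surface and cross-phantom
# vertex homology. The geometry emulates the situation the comparative
# analysis assumes: several longitudinal bundles running along the y axis
# ("anteroposterior"), terminating in a gray-matter plate at the posterior
# end of the grid whose border carries the cortical surface.

#' Create a bundle specification
#'
#' @param label bundle identifier.
#' @param centerline `n x 2` or `n x 3` matrix of control points in voxel
#'   coordinates.  Two-column input is interpreted as (x, z) with the
#'   centerline spanning the full white-matter extent along y.
#' @param radiusVox tube radius in voxels (>= 1).
#' @param splitInto optional character(2) of child labels; the bundle is then
#'   generated as two parallel child tubes.
#' @param splitOffsets `2 x 3` matrix of per-child centerline offsets
#'   (voxels); defaults to a symmetric lateral (+/- 2 radius) split along x.
#' @param curved marker for curved (arcuate-like) geometry; informational.
#' @return A [BundleSpec-class].
#' @export
bundleSpec <- function(label, centerline, radiusVox = 2.5, splitInto = character(),
                       splitOffsets = NULL, curved = FALSE) {
  centerline <- as.matrix(centerline)
  if (is.null(splitOffsets)) {
    splitOffsets <- rbind(c(2 * radiusVox + 1, 0, 0), c(-(2 * radiusVox + 1), 0, 0))
  }
  new("BundleSpec", label = as.character(label), centerline = centerline,
      radiusVox = as.numeric(radiusVox), splitInto = as.character(splitInto),
      splitOffsets = as.matrix(splitOffsets), curved = isTRUE(curved))
}

#' Create a phantom specification
#'
#' @param bundles list of [BundleSpec-class].
#' @param gridShape integer(3), all >= 16.
#' @param voxelSize voxel edge length in mm.
#' @param gmThickness gray-matter plate thickness in voxels.
#' @param dispersionDeg angular standard deviation of orientation noise
#'   (degrees).
#' @param subjectJitterVox per-subject rigid centerline displacement scale
#'   (voxels).
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(bundles, gridShape = c(40L, 40L, 40L), voxelSize = 1,
                        gmThickness = 3L, dispersionDeg = 10,
                        subjectJitterVox = 1, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), bundles = bundles,
      gmThickness = as.integer(gmThickness),
      dispersionDeg = as.numeric(dispersionDeg),
      subjectJitterVox = as.numeric(subjectJitterVox), seed = as.integer(seed))
}

#' Canonical demonstration phantom layouts
#'
#' Ready-made bundle inventories on a 40^3 grid that emulate the qualitative
#' species differences the pipeline is designed to detect:
#' * `"three-straight"`: three parallel longitudinal bundles (analogues of
#'   MdLF, IFOF and an unsplit ILF) — the monkey-like layout.
#' * `"split-ilf"`: the same, but the ILF-analogue is split into a lateral
#'   and a medial child bundle; the medial child is congruent with the
#'   unsplit parent of `"three-straight"` — the hominid-like layout.
#' * `"with-arcuate"`: `"split-ilf"` plus a curved dorsal (arcuate-like)
#'   bundle absent from the other layouts.
#'
#' @param layout one of `"three-straight"`, `"split-ilf"`, `"with-arcuate"`.
#' @param seed integer RNG seed.
#' @param dispersionDeg angular noise (degrees).
#' @param subjectJitterVox inter-subject jitter scale (voxels).
#' @return A [PhantomSpec-class].
#' @export
demoPhantomSpec <- function(layout = c("three-straight", "split-ilf", "with-arcuate"),
                            seed = 1L, dispersionDeg = 10, subjectJitterVox = 1) {
  layout <- match.arg(layout)
  g <- c(40L, 40L, 40L)
  # Straight bundles as (x, z) cross-section centers; y handled by expansion.
  # The tubes are adjacent (edge gaps of a few voxels), as the temporal
  # longitudinal tracts are, so that orientation dispersion produces the
  # partially overlapping territories and mixed fingerprints the blueprint
  # comparison assumes.
  mdlf <- bundleSpec("mdlf", cbind(13, 29), radiusVox = 2.5)
  ifof <- bundleSpec("ifof", cbind(21, 24), radiusVox = 2.5)
  ilf <- bundleSpec("ilf", cbind(26, 28), radiusVox = 2.5)
  if (layout != "three-straight") {
    # Children: lateral child shifted +6 in x, medial child congruent with
    # the unsplit parent (offset 0), mirroring a medial subcomponent that
    # retains the ancestral course.
    ilf <- bundleSpec("ilf", cbind(26, 28), radiusVox = 2.5,
                      splitInto = c("ilf_lat", "ilf_med"),
                      splitOffsets = rbind(c(6, 0, 0), c(0, 0, 0)))
  }
  bundles <- list(mdlf, ifof, ilf)
  if (layout == "with-arcuate") {
    # Curved dorsal bundle: runs along y at x = 6 beside the mdlf tube,
    # rising from z = 20 to a distinct cortical territory at z = 34.
    yy <- seq(1, 37, length.out = 10)
    zz <- 20 + 14 * (yy - 1)^2 / (36^2)
    af <- bundleSpec("arcuate", cbind(6, yy, zz), radiusVox = 2.5, curved = TRUE)
    bundles <- c(bundles, list(af))
  }
  phantomSpec(bundles, gridShape = g, dispersionDeg = dispersionDeg,
              subjectJitterVox = subjectJitterVox, seed = seed)
}

# Expand split bundles into concrete tubes; returns a list of lists with
# label, centerline (n x 3), radius, parent label.
.expandBundles <- function(spec) {
  out <- list()
  wmTop <- spec@gridShape[2L] - spec@gmThickness  # last white-matter y slice
  for (b in spec@bundles) {
    cl <- b@centerline
    if (ncol(cl) == 2L) {
      # (x, z) cross-section: span the full white-matter y extent.
      cl <- rbind(c(cl[1L, 1L], 0.5, cl[1L, 2L]),
                  c(cl[1L, 1L], wmTop + 0.5, cl[1L, 2L]))
    }
    if (length(b@splitInto)) {
      for (i in 1:2) {
        out[[length(out) + 1L]] <- list(
          label = b@splitInto[i],
          centerline = sweep(cl, 2L, b@splitOffsets[i, ], `+`),
          radius = b@radiusVox, parent = b@label)
      }
    } else {
      out[[length(out) + 1L]] <- list(label = b@label, centerline = cl,
                                      radius = b@radiusVox, parent = b@label)
    }
  }
  out
}

# Densely resample a polyline at ~0.25-voxel arc-length spacing; returns
# points and unit tangents.
.resampleCenterline <- function(cl, spacing = 0.25) {
  segs <- diff(cl)
  lens <- sqrt(rowSums(segs^2))
  pts <- list(); tans <- list()
  for (i in seq_len(nrow(segs))) {
    n <- max(2L, ceiling(lens[i] / spacing) + 1L)
    tt <- seq(0, 1, length.out = n)
    if (i < nrow(segs)) tt <- tt[-n]
    p <- cbind(cl[i, 1L] + tt * segs[i, 1L], cl[i, 2L] + tt * segs[i, 2L],
               cl[i, 3L] + tt * segs[i, 3L])
    pts[[i]] <- p
    tans[[i]] <- matrix(segs[i, ] / lens[i], nrow(p), 3L, byrow = TRUE)
  }
  list(points = do.call(rbind, pts), tangents = do.call(rbind, tans))
}

#' Generate a species phantom
#'
#' Builds the orientation field, tissue masks, bundle label volume,
#' gray/white border surface and vertex ground truth from a phantom
#' specification.  The orientation at each bundle voxel is the local
#' centerline tangent perturbed by folded-normal angular noise of scale
#' `dispersionDeg` about a uniformly random perpendicular axis; background
#' white matter is isotropic.  The same spec and seed always reproduce the
#' identical phantom bit for bit.
#'
#' @param spec a [PhantomSpec-class].
#' @param jitter optional `nBundles x 3` matrix of rigid centerline offsets
#'   (used by [generateCohort()]); `NULL` for none.
#' @param seed RNG seed override (defaults to `spec@seed`).
#' @return A [SpeciesPhantom-class].
#' @export
generatePhantom <- function(spec, jitter = NULL, seed = spec@seed) {
  validObject(spec)
  g <- spec@gridShape
  nvox <- prod(g)
  wmTop <- g[2L] - spec@gmThickness
  if (wmTop < 4L) .stopf("gray-matter plate leaves too little white matter")

  tubes <- .expandBundles(spec)
  if (!is.null(jitter)) {
    if (nrow(jitter) != length(tubes)) .stopf("jitter must have one row per bundle tube")
    for (i in seq_along(tubes))
      tubes[[i]]$centerline <- sweep(tubes[[i]]$centerline, 2L, jitter[i, ], `+`)
  }

  labels <- integer(nvox)
  tangent <- matrix(0, nvox, 3L)
  labelNames <- vapply(tubes, `[[`, character(1), "label")
  parentNames <- vapply(tubes, `[[`, character(1), "parent")

  # Voxel centers, for tube membership tests.
  cx <- (seq_len(g[1L]) - 0.5)
  for (ti in seq_along(tubes)) {
    tube <- tubes[[ti]]
    rs <- .resampleCenterline(tube$centerline)
    r <- tube$radius
    lo <- apply(rs$points, 2L, min) - r
    hi <- apply(rs$points, 2L, max) + r
    # the tube must stay inside the grid laterally; its ends may touch the
    # grid/gm boundaries along y (bundles are longitudinal by construction)
    if (lo[1L] < 0 || lo[3L] < 0 || hi[1L] > g[1L] || hi[3L] > g[3L] ||
        min(rs$points[, 2L]) < -0.5 || max(rs$points[, 2L]) > g[2L] + 0.5)
      .stopf("bundle '%s' leaves the grid", tube$label)
    xs <- max(1L, floor(lo[1L])):min(g[1L], ceiling(hi[1L]))
    ys <- max(1L, floor(lo[2L])):min(wmTop, ceiling(hi[2L]))
    zs <- max(1L, floor(lo[3L])):min(g[3L], ceiling(hi[3L]))
    cand <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    cc <- cand - 0.5
    # nearest centerline sample per candidate voxel (candidate sets are small)
    np <- nrow(rs$points)
    best <- rep(Inf, nrow(cc)); bestIdx <- rep(1L, nrow(cc))
    for (j in seq_len(np)) {
      d2 <- (cc[, 1L] - rs$points[j, 1L])^2 + (cc[, 2L] - rs$points[j, 2L])^2 +
        (cc[, 3L] - rs$points[j, 3L])^2
      upd <- d2 < best
      best[upd] <- d2[upd]; bestIdx[upd] <- j
    }
    inside <- best <= r^2
    if (!any(inside)) .stopf("bundle '%s' produced no voxels", tube$label)
    idx <- .linIdx(cand[inside, , drop = FALSE], g)
    clash <- labels[idx] != 0L
    if (any(clash)) {
      other <- labelNames[labels[idx[clash][1L]]]
      .stopf("bundle tubes overlap with distinct labels: '%s' and '%s'",
             other, tube$label)
    }
    labels[idx] <- ti
    tangent[idx, ] <- rs$tangents[bestIdx[inside], , drop = FALSE]
  }

  # Orientation noise: folded-normal rotation about a random perpendicular axis.
  set.seed(seed)
  oriented <- which(labels > 0L)
  o <- .canonicalSign(.unitRows(tangent[oriented, , drop = FALSE]))
  if (spec@dispersionDeg > 0 && length(oriented)) {
    theta <- abs(qnorm(.clampU(runif(length(oriented))))) * spec@dispersionDeg * pi / 180
    phi <- 2 * pi * runif(length(oriented))
    pb <- .perpBasis(o)
    o <- .canonicalSign(cos(theta) * o +
      sin(theta) * (cos(phi) * pb$e1 + sin(phi) * pb$e2))
  }
  orientations <- array(0, c(nvox, 1L, 3L))
  orientations[oriented, 1L, ] <- o
  weights <- matrix(0, nvox, 1L)
  weights[oriented, 1L] <- 1

  gm <- array(FALSE, g); gm[, (wmTop + 1L):g[2L], ] <- TRUE
  wm <- array(FALSE, g); wm[, 1L:wmTop, ] <- TRUE
  isotropic <- rep(TRUE, nvox)
  isotropic[oriented] <- FALSE
  isotropic[as.vector(gm)] <- FALSE  # gm voxels are never sampled (termination)

  field <- new("OrientationField", dim = g, voxelSize = spec@voxelSize,
               orientations = orientations, weights = weights,
               dispersionDeg = spec@dispersionDeg, isotropic = isotropic)

  # Surface: the plane of faces between the last wm slice and the first gm
  # slice.  One vertex per (x, z) face center, quads split into triangles.
  yB <- wmTop  # boundary plane in voxel units (mm = yB * voxelSize)
  nxv <- g[1L]; nzv <- g[3L]
  vx <- rep(seq_len(nxv) - 0.5, times = nzv)
  vz <- rep(seq_len(nzv) - 0.5, each = nxv)
  vertices <- cbind(vx, yB, vz) * spec@voxelSize
  dimnames(vertices) <- NULL
  vid <- function(i, k) (k - 1L) * nxv + i
  fi <- rep(seq_len(nxv - 1L), times = nzv - 1L)
  fk <- rep(seq_len(nzv - 1L), each = nxv - 1L)
  a <- vid(fi, fk); b <- vid(fi + 1L, fk); cc2 <- vid(fi + 1L, fk + 1L); d <- vid(fi, fk + 1L)
  faces <- rbind(cbind(a, b, cc2), cbind(a, cc2, d))
  surface <- new("SurfaceMesh", vertices = vertices,
                 faces = matrix(as.integer(faces), ncol = 3L))

  # Vertex ground truth: the bundle whose tube contains the point just below
  # the boundary at the vertex (x, z).
  nv <- nrow(vertices)
  vertexTruth <- integer(nv)
  probe <- cbind(vx, yB - 0.5, vz)  # center of the adjacent wm voxel
  pv <- .posToVox(probe)
  vertexTruth <- labels[.linIdx(pv, g)]
  homologyId <- seq_len(nv)

  labelTable <- data.frame(id = seq_along(labelNames), label = labelNames,
                           parent = parentNames, stringsAsFactors = FALSE)
  labArr <- array(labels, g)
  phant <- new("SpeciesPhantom", field = field, wmMask = wm, gmMask = gm,
               bundleLabels = labArr, labelTable = labelTable, surface = surface,
               vertexTruth = as.integer(vertexTruth),
               homologyId = as.integer(homologyId), spec = spec)
  validObject(phant)
  phant
}

#' Generate a multi-subject cohort of phantoms
#'
#' Subject `i` is generated with seed `spec@seed + i - 1` and all bundle
#' centerlines rigidly displaced together in the (x, z) plane by Gaussian
#' jitter of scale `subjectJitterVox` (clamped at 2.5 sd), emulating the
#' anatomical offset between the subjects whose tract distributions are
#' later averaged while preserving the declared bundle adjacency.  All
#' subjects share the homology-id assignment.
#'
#' @param spec a [PhantomSpec-class].
#' @param nSubjects number of subjects (>= 1).
#' @return List of [SpeciesPhantom-class].
#' @export
generateCohort <- function(spec, nSubjects) {
  if (nSubjects < 1L) .stopf("nSubjects must be >= 1")
  nTubes <- length(.expandBundles(spec))
  lapply(seq_len(nSubjects), function(i) {
    sdi <- spec@seed + i - 1L
    jit <- matrix(0, nTubes, 3L)
    if (spec@subjectJitterVox > 0) {
      set.seed((sdi %% 1073741823L) * 2L + 1L)  # jitter stream, separate from orientation noise
      s <- spec@subjectJitterVox
      j <- pmin(pmax(stats::rnorm(2L, sd = s), -2.5 * s), 2.5 * s)
      jit <- matrix(rep(c(j[1L], 0, j[2L]), each = nTubes), nTubes, 3L)
    }
    generatePhantom(spec, jitter = jit, seed = sdi)
  })
}

#' Ground-truth surface footprint of a bundle
#'
#' The vertices lying over a bundle's course: the bundle's labeled voxels
#' are projected along the y axis onto the surface plate and dilated
#' laterally, giving the ground-truth surface territory a dorsal or
#' longitudinal bundle can reach.
#'
#' @param phantom a [SpeciesPhantom-class].
#' @param label bundle label.
#' @param dilateVox lateral dilation in voxels (accounts for orientation
#'   dispersion).
#' @return Logical per-vertex mask.
#' @export
bundleFootprint <- function(phantom, label, dilateVox = 2) {
  id <- phantom@labelTable$id[match(label, phantom@labelTable$label)]
  if (is.na(id)) .stopf("unknown bundle '%s'", label)
  d <- dim(phantom@bundleLabels)
  fp <- apply(phantom@bundleLabels == id, c(1L, 3L), any)
  xz <- which(fp, arr.ind = TRUE)
  v <- phantom@surface@vertices / phantom@field@voxelSize
  out <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    dx <- abs(v[i, 1L] - (xz[, 1L] - 0.5))
    dz <- abs(v[i, 3L] - (xz[, 2L] - 0.5))
    out[i] <- any(pmax(dx, dz) <= dilateVox)
  }
  out
}

#' Build a matched phantom pair with known vertex correspondence
#'
#' Generates both phantoms and returns the homology-based vertex
#' correspondence restricted to labeled vertices.  `labelMap` declares which
#' bundle of phantom A corresponds to which bundle (or split pair) of
#' phantom B; bundles of B absent from the map (for example an arcuate-like
#' bundle present in only one phantom) yield vertices flagged as having no
#' counterpart.
#'
#' @param specA,specB [PhantomSpec-class] sharing `gridShape`.
#' @param labelMap named list: names are A-labels, values character vectors
#'   of corresponding B-labels.  Defaults to the identity on shared labels.
#' @return List with elements `a`, `b` ([SpeciesPhantom-class]) and
#'   `correspondence`, a data.frame with columns `vertex`, `labelA`,
#'   `labelB`, `hasCounterpart`.
#' @export
matchedPair <- function(specA, specB, labelMap = NULL) {
  if (!identical(specA@gridShape, specB@gridShape))
    .stopf("matched specs must share gridShape")
  a <- generatePhantom(specA)
  b <- generatePhantom(specB)
  labsA <- a@labelTable$label
  labsB <- b@labelTable$label
  if (is.null(labelMap)) {
    shared <- intersect(labsA, labsB)
    labelMap <- setNames(as.list(shared), shared)
    # map unsplit parents in A onto their children in B (and vice versa)
    for (la in setdiff(labsA, shared)) {
      kidsB <- labsB[b@labelTable$parent == la]
      if (length(kidsB)) labelMap[[la]] <- kidsB
    }
  }
  unmappedA <- setdiff(labsA, names(labelMap))
  if (length(unmappedA))
    .stopf("unmappable labels in phantom A: %s", paste(unmappedA, collapse = ", "))
  bad <- setdiff(unlist(labelMap), labsB)
  if (length(bad))
    .stopf("label map names bundles absent from phantom B: %s",
           paste(bad, collapse = ", "))

  # Vertex-level correspondence: same homology id (same grid position).
  nv <- nrow(a@surface@vertices)
  truthA <- rep(NA_character_, nv)
  truthA[a@vertexTruth > 0L] <- a@labelTable$label[a@vertexTruth[a@vertexTruth > 0L]]
  truthB <- rep(NA_character_, nv)
  truthB[b@vertexTruth > 0L] <- b@labelTable$label[b@vertexTruth[b@vertexTruth > 0L]]
  lab <- which(!is.na(truthA) | !is.na(truthB))
  has <- logical(length(lab))
  for (i in seq_along(lab)) {
    v <- lab[i]
    la <- truthA[v]; lb <- truthB[v]
    if (!is.na(la) && !is.na(lb)) {
      has[i] <- lb %in% labelMap[[la]]
    } else if (is.na(la) && !is.na(lb)) {
      # B-only label: counterpart exists only if some A bundle maps onto it
      has[i] <- lb %in% unlist(labelMap)
    } else {
      has[i] <- FALSE
    }
  }
  corr <- data.frame(vertex = lab, labelA = truthA[lab], labelB = truthB[lab],
                     hasCounterpart = has, stringsAsFactors = FALSE)
  list(a = a, b = b, correspondence = corr)
}
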