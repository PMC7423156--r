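# Connectivity blueprints: vertex-by-tract matrices whose rows are the
# connectivity fingerprints of cortical vertices, built as the product of a
# vertexwise connectivity matrix (surface -> volume) and a tract matrix
# (volume -> tract).

#' Vertexwise connectivity matrix
#'
#' Launches unconstrained tractography (termination at gray matter) from the
#' white-matter voxel adjacent to each surface vertex and collects
#' binary-per-streamline visitation counts, one row per vertex.  Vertices
#' with no adjacent white matter get a zero row and a warning.
#'
#' @param surface a [SurfaceMesh-class] whose vertices lie on the gray/white
#'   border.
#' @param field an [OrientationField-class].
#' @param params a [TrackingParams-class]; `nSamples` streamlines are
#'   launched per vertex.
#' @param wmMask,gmMask logical volumes (seeding and termination).
#' @return A [VertexConnectivity-class].
#' @export
vertexConnectivity <- function(surface, field, params, wmMask, gmMask) {
  dimg <- field@dim
  nv <- nrow(surface@vertices)
  p <- surface@vertices / field@voxelSize  # voxel units
  v0 <- .posToVox(p)
  # A vertex sits on a voxel face; find the adjacent white-matter voxel,
  # preferring the -y neighbor (the interior side of the gray-matter plate).
  offsets <- rbind(c(0, -1, 0), c(0, 0, 0), c(0, 1, 0),
                   c(-1, 0, 0), c(1, 0, 0), c(0, 0, -1), c(0, 0, 1))
  seedVox <- rep(NA_integer_, nv)
  for (o in seq_len(nrow(offsets))) {
    cand <- sweep(v0, 2L, offsets[o, ], `+`)
    okRow <- is.na(seedVox) & .inGrid(cand, dimg)
    if (!any(okRow)) next
    li <- .linIdx(cand[okRow, , drop = FALSE], dimg)
    hit <- which(okRow)[wmMask[li]]
    seedVox[hit] <- .linIdx(cand[hit, , drop = FALSE], dimg)
  }
  noWm <- which(is.na(seedVox))
  if (length(noWm))
    .warnf("%d vertices have no adjacent white matter: zero rows", length(noWm))
  withWm <- which(!is.na(seedVox))

  nPer <- params@nSamples
  starts <- .voxCoord(rep(seedVox[withWm], each = nPer), dimg) - 1L
  signs <- rep(rep(c(1, -1), length.out = nPer), length(withWm))
  vertexOf <- rep(withWm, each = nPer)
  N <- nrow(starts)
  streamSeeds <- NULL
  if (params@mode == "probabilistic") {
    set.seed(params@seed)
    streamSeeds <- sample.int(2147483646L, N)
  }
  res <- .trackCore(field, matrix(as.numeric(starts), ncol = 3L), signs, params,
                    terminationMask = gmMask, jitterStart = TRUE,
                    streamSeeds = streamSeeds)
  mat <- Matrix::sparseMatrix(
    i = vertexOf[res$visits$stream], j = res$visits$vox, x = 1,
    dims = c(nv, prod(dimg)))
  new("VertexConnectivity", matrix = mat, surface = surface, params = params)
}

#' Concatenate tractograms into a voxel-by-tract matrix
#'
#' @param tractograms named list of [Tractogram-class] (or numeric volumes);
#'   columns take the protocol names (or the list names).
#' @return `nvox x T` matrix of normalized tract maps.
#' @export
tractMatrix <- function(tractograms) {
  cols <- lapply(tractograms, function(t)
    if (is(t, "Tractogram")) as.vector(t@normalized) else as.vector(t))
  nms <- names(tractograms)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- vapply(tractograms, function(t)
      if (is(t, "Tractogram")) t@protocolName else "", character(1))
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

#' Build a connectivity blueprint
#'
#' Multiplies the vertexwise connectivity matrix (surface space by volume
#' space) with the tract matrix (volume space by tract space) and normalizes
#' each row to sum 1, turning each row into the probability distribution of
#' the vertex being reached by each tract.  All-zero rows stay zero and are
#' flagged.
#'
#' @param vc a [VertexConnectivity-class] or plain `nv x nvox` matrix.
#' @param tractMat `nvox x T` matrix with tract-name column names.
#' @return A [Blueprint-class].
#' @export
buildBlueprint <- function(vc, tractMat) {
  M <- if (is(vc, "VertexConnectivity")) vc@matrix else vc
  if (ncol(M) != nrow(tractMat)) .stopf("inner dimensions do not match")
  raw <- as.matrix(M %*% tractMat)
  rs <- rowSums(raw)
  zero <- rs == 0
  norm <- raw
  norm[!zero, ] <- raw[!zero, , drop = FALSE] / rs[!zero]
  tn <- colnames(tractMat)
  if (is.null(tn)) tn <- paste0("tract", seq_len(ncol(tractMat)))
  new("Blueprint", matrix = norm, raw = raw, tractNames = tn,
      vertexIds = seq_len(nrow(raw)), zeroRows = zero)
}

#' Surface projection of one tract
#'
#' Extracts the raw (pre-normalization) column of the blueprint for one
#' tract: the per-vertex scalar map used for surface display.
#'
#' @param bp a [Blueprint-class].
#' @param tract tract name.
#' @return Named numeric per-vertex map.
#' @export
surfaceProjection <- function(bp, tract) {
  j <- match(tract, bp@tractNames)
  if (is.na(j)) .stopf("unknown tract '%s'", tract)
  setNames(bp@raw[, j], bp@vertexIds)
}

# Edge list (unique, both orders) from a face matrix.
.meshEdges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)])
  e <- unique(rbind(e, e[, 2:1]))
  e[e[, 1L] != e[, 2L], , drop = FALSE]
}

#' Smooth a per-vertex map on the mesh
#'
#' Iterative symmetric neighbor diffusion whose accumulated variance matches
#' a Gaussian kernel of the requested full width at half maximum
#' (sd = fwhm / 2.3548).  Constant maps are preserved exactly, the total sum
#' is conserved, and `fwhmMm = 0` is the identity; isolated vertices are
#' left unchanged.
#'
#' @param surface a [SurfaceMesh-class].
#' @param values numeric per-vertex map.
#' @param fwhmMm kernel FWHM in mm (>= 0).
#' @return Smoothed per-vertex map.
#' @export
smoothSurfaceMap <- function(surface, values, fwhmMm) {
  if (fwhmMm < 0) .stopf("fwhm must be >= 0")
  nv <- nrow(surface@vertices)
  if (length(values) != nv) .stopf("values must have one entry per vertex")
  if (fwhmMm == 0) return(values)
  edges <- .meshEdges(surface@faces)
  if (!nrow(edges)) return(values)
  h <- mean(sqrt(rowSums((surface@vertices[edges[, 1L], , drop = FALSE] -
                            surface@vertices[edges[, 2L], , drop = FALSE])^2)))
  A <- Matrix::sparseMatrix(i = edges[, 1L], j = edges[, 2L], x = 1,
                            dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  lambda <- 0.125
  sigma <- fwhmMm / 2.3548
  nIter <- max(1L, as.integer(round(sigma^2 / (2 * lambda * h^2))))
  v <- values
  for (i in seq_len(nIter)) v <- v + lambda * (as.vector(A %*% v) - deg * v)
  v
}

#' Restrict a blueprint to a vertex mask
#'
#' Drops the rows outside the mask while retaining the original vertex ids,
#' mirroring the restriction of the analysis to a lobe of interest.
#'
#' @param bp a [Blueprint-class].
#' @param vertexMask logical of length `nrow(bp)` or integer vertex ids.
#' @return A [Blueprint-class] with the retained rows unchanged.
#' @export
maskBlueprint <- function(bp, vertexMask) {
  keep <- if (is.logical(vertexMask)) {
    if (length(vertexMask) != nrow(bp@matrix))
      .stopf("mask length must equal the vertex count")
    which(vertexMask)
  } else {
    match(vertexMask, bp@vertexIds)
  }
  if (!length(keep) || anyNA(keep)) .stopf("empty or invalid vertex mask")
  new("Blueprint", matrix = bp@matrix[keep, , drop = FALSE],
      raw = bp@raw[keep, , drop = FALSE], tractNames = bp@tractNames,
      vertexIds = bp@vertexIds[keep], zeroRows = bp@zeroRows[keep])
}

#' Tract territory on the surface
#'
#' Vertices whose smoothed, log-normalized surface projection of a tract
#' exceeds the display threshold — the surface analogue of a thresholded
#' tract figure, used to define masks such as "the territory of the
#' inferior longitudinal bundle".
#'
#' @param bp a [Blueprint-class].
#' @param surface the matching [SurfaceMesh-class].
#' @param tract tract name.
#' @param fwhmMm smoothing kernel FWHM (mm).
#' @param threshold display threshold after log-normalization.
#' @return Logical per-vertex mask (over `bp@vertexIds`).
#' @export
tractTerritory <- function(bp, surface, tract, fwhmMm = 2, threshold = 0.7) {
  proj <- surfaceProjection(bp, tract)
  full <- numeric(nrow(surface@vertices))
  full[bp@vertexIds] <- proj
  sm <- smoothSurfaceMap(surface, full, fwhmMm)
  ln <- logNormalize(array(sm, c(length(sm), 1L, 1L)))
  mask <- as.vector(ln) >= threshold
  mask[bp@vertexIds]
}
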