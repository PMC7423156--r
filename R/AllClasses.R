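#' @import methods
#' @importFrom stats cor kmeans ks.test qnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

#' Fiber orientation field
#'
#' Per-voxel set of undirected unit orientations with mixture weights and a
#' global angular dispersion, the substrate that streamline tractography
#' samples from.  Orientations are stored axially (no polarity) with the sign
#' convention that the first nonzero component is positive.  Voxels flagged
#' `isotropic` carry no preferred orientation: probabilistic tracking draws a
#' uniformly random direction there, modeling unstructured background white
#' matter.
#'
#' @slot dim integer(3), grid shape in voxels.
#' @slot voxelSize numeric(1), isotropic voxel edge length in mm.
#' @slot orientations array `c(nvox, K, 3)` of unit vectors (canonical sign).
#' @slot weights `nvox x K` matrix of non-negative mixture weights; rows of
#'   non-isotropic voxels sum to 1.
#' @slot dispersionDeg numeric(1), angular standard deviation (degrees) used
#'   when re-perturbing sampled orientations.
#' @slot isotropic logical(nvox), background voxels with no stored orientation.
#' @export
setClass("OrientationField", representation(
  dim = "integer", voxelSize = "numeric", orientations = "array",
  weights = "matrix", dispersionDeg = "numeric", isotropic = "logical"
), validity = function(object) {
  msg <- character()
  nvox <- as.integer(prod(object@dim))
  if (length(object@dim) != 3L) msg <- c(msg, "dim must have length 3")
  if (!identical(dim(object@orientations)[c(1L, 3L)], c(nvox, 3L)))
    msg <- c(msg, "orientations must be an nvox x K x 3 array")
  if (nrow(object@weights) != nvox) msg <- c(msg, "weights must have nvox rows")
  if (object@dispersionDeg < 0) msg <- c(msg, "dispersionDeg must be >= 0")
  if (length(object@isotropic) != nvox) msg <- c(msg, "isotropic must have length nvox")
  oriented <- which(!object@isotropic)
  if (length(oriented)) {
    K <- dim(object@orientations)[2L]
    for (k in seq_len(K)) {
      w <- object@weights[oriented, k]
      o <- object@orientations[oriented, k, , drop = FALSE]
      nrm <- sqrt(o[, 1, 1]^2 + o[, 1, 2]^2 + o[, 1, 3]^2)
      bad <- w > 0 & abs(nrm - 1) > 1e-9
      if (any(bad)) msg <- c(msg, "weighted orientations must have unit norm (1e-9)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Triangulated surface mesh
#'
#' A gray/white-matter border surface: vertex coordinates in mm and triangle
#' faces.  Vertex adjacency (used for surface smoothing) is derived from the
#' face list.
#'
#' @slot vertices `nv x 3` matrix of coordinates (mm).
#' @slot faces `nf x 3` integer matrix of vertex index triples (1-based).
#' @export
setClass("SurfaceMesh", representation(
  vertices = "matrix", faces = "matrix"
), validity = function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must have 3 columns")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must have 3 columns")
  if (nrow(object@faces) &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "faces index vertices outside the mesh")
  if (length(msg)) msg else TRUE
})

#' Bundle specification
#'
#' One synthetic fiber bundle: a tube of radius `radiusVox` around an ordered
#' centerline.  A bundle may be split into two child bundles (modeling the
#' lateral/medial subcomponents of an inferior longitudinal bundle): each
#' child reuses the parent centerline shifted by one row of `splitOffsets`.
#'
#' @slot label character(1) bundle identifier.
#' @slot centerline `n x 3` matrix of control points (voxel coordinates).
#' @slot radiusVox numeric(1) tube radius in voxels, >= 1.
#' @slot splitInto character(2) child labels, or character(0) for no split.
#' @slot splitOffsets `2 x 3` matrix of child centerline offsets (voxels).
#' @slot curved logical(1) marker for curved (arcuate-like) geometry.
#' @export
setClass("BundleSpec", representation(
  label = "character", centerline = "matrix", radiusVox = "numeric",
  splitInto = "character", splitOffsets = "matrix", curved = "logical"
), validity = function(object) {
  msg <- character()
  if (ncol(object@centerline) == 3L && nrow(object@centerline) < 2L)
    msg <- c(msg, "centerline needs >= 2 points")
  if (ncol(object@centerline) == 2L && nrow(object@centerline) < 1L)
    msg <- c(msg, "cross-section centerline needs a point")
  if (!ncol(object@centerline) %in% c(2L, 3L))
    msg <- c(msg, "centerline must have 2 (x,z) or 3 (x,y,z) columns")
  if (object@radiusVox < 1) msg <- c(msg, "radiusVox must be >= 1")
  if (length(object@splitInto) && length(object@splitInto) != 2L)
    msg <- c(msg, "splitInto must name exactly two children")
  if (length(msg)) msg else TRUE
})

#' Phantom specification
#'
#' Everything needed to generate one synthetic "species" brain
#' deterministically: grid geometry, the bundle inventory, gray-matter plate
#' thickness, orientation noise, inter-subject jitter and the RNG seed.
#'
#' @slot gridShape integer(3) grid shape (all >= 16).
#' @slot voxelSize numeric(1) mm.
#' @slot bundles list of [BundleSpec-class] with unique labels.
#' @slot gmThickness integer(1) gray-matter plate thickness in voxels.
#' @slot dispersionDeg numeric(1) angular sd of orientation noise (degrees).
#' @slot subjectJitterVox numeric(1) per-subject centerline displacement scale.
#' @slot seed integer(1) RNG seed.
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer", voxelSize = "numeric", bundles = "list",
  gmThickness = "integer", dispersionDeg = "numeric",
  subjectJitterVox = "numeric", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
    msg <- c(msg, "gridShape must be three values >= 16")
  if (object@dispersionDeg < 0) msg <- c(msg, "dispersionDeg must be >= 0")
  if (!length(object@bundles)) msg <- c(msg, "bundles must be non-empty")
  labs <- vapply(object@bundles, function(b) b@label, character(1))
  if (anyDuplicated(labs)) msg <- c(msg, "bundle labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Synthetic species phantom
#'
#' A generated phantom brain: its orientation field, tissue masks, bundle
#' label volume, gray/white border surface, and the per-vertex ground truth
#' that downstream recovery tests are scored against.  `homologyId` is shared
#' across phantoms generated on the same grid and encodes the known
#' vertex-to-vertex correspondence between matched phantoms.
#'
#' @slot field [OrientationField-class].
#' @slot wmMask,gmMask logical volumes (disjoint).
#' @slot bundleLabels integer volume, 0 = background.
#' @slot labelTable data.frame mapping label ids to bundle names.
#' @slot surface [SurfaceMesh-class] at the gray/white border.
#' @slot vertexTruth integer per-vertex ground-truth bundle id (0 = none).
#' @slot homologyId integer per-vertex correspondence key.
#' @slot spec the [PhantomSpec-class] it was generated from.
#' @export
setClass("SpeciesPhantom", representation(
  field = "OrientationField", wmMask = "array", gmMask = "array",
  bundleLabels = "array", labelTable = "data.frame", surface = "SurfaceMesh",
  vertexTruth = "integer", homologyId = "integer", spec = "PhantomSpec"
), validity = function(object) {
  msg <- character()
  if (any(object@wmMask & object@gmMask)) msg <- c(msg, "gm and wm masks must be disjoint")
  if (any(object@bundleLabels > 0 & !object@wmMask))
    msg <- c(msg, "labeled voxels must lie in the white-matter mask")
  nv <- nrow(object@surface@vertices)
  if (length(object@vertexTruth) != nv || length(object@homologyId) != nv)
    msg <- c(msg, "vertexTruth/homologyId must match the vertex count")
  if (length(msg)) msg else TRUE
})

#' Tracking parameters
#'
#' Settings of the streamline propagator.  Defaults follow the common
#' probabilistic-tractography configuration for these protocols: 10,000
#' streamline samples per seed voxel, a 2,000-step cap, a curvature threshold
#' of 0.2 (minimum cosine between successive step directions) and a 0.5 mm
#' step.  Desk-scale analyses pass smaller `nSamples` explicitly.
#'
#' @slot nSamples integer(1) streamlines per seed voxel.
#' @slot maxSteps integer(1) step cap per streamline.
#' @slot stepLength numeric(1) mm.
#' @slot curvatureThreshold numeric(1) in `[0, 1]`.
#' @slot mode `"probabilistic"` or `"deterministic"`.
#' @slot seed integer(1) base RNG seed for this run.
#' @export
setClass("TrackingParams", representation(
  nSamples = "integer", maxSteps = "integer", stepLength = "numeric",
  curvatureThreshold = "numeric", mode = "character", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@maxSteps < 1L) msg <- c(msg, "maxSteps must be >= 1")
  if (object@stepLength <= 0) msg <- c(msg, "stepLength must be > 0")
  if (object@curvatureThreshold < 0 || object@curvatureThreshold > 1)
    msg <- c(msg, "curvatureThreshold must be in [0, 1]")
  if (!object@mode %in% c("probabilistic", "deterministic"))
    msg <- c(msg, "mode must be 'probabilistic' or 'deterministic'")
  if (length(msg)) msg else TRUE
})

#' Tract protocol
#'
#' Seed, waypoint, exclusion and termination masks plus tracking parameters
#' for one tract.  Streamlines start in the seed; they are retained only if
#' they cross at least one waypoint (OR logic), deleted on contact with any
#' exclusion mask, and stopped (but kept) on entering the termination mask.
#'
#' @slot name character(1) tract identifier.
#' @slot seedMask logical volume, non-empty.
#' @slot waypointMasks list of logical volumes (may be empty: no retention
#'   constraint).
#' @slot exclusionMasks list of logical volumes.
#' @slot terminationMask logical volume (possibly all-FALSE).
#' @slot params [TrackingParams-class].
#' @export
setClass("TractProtocol", representation(
  name = "character", seedMask = "array", waypointMasks = "list",
  exclusionMasks = "list", terminationMask = "array", params = "TrackingParams"
), validity = function(object) {
  msg <- character()
  if (!any(object@seedMask)) msg <- c(msg, "seed mask must be non-empty")
  for (ex in object@exclusionMasks)
    if (any(object@seedMask & ex)) msg <- c(msg, "seed must be disjoint from exclusion masks")
  if (length(msg)) msg else TRUE
})

#' Tractogram
#'
#' Streamline visitation counts for one protocol run.  Each retained
#' streamline increments a voxel at most once, so `normalized` (counts
#' divided by the number of retained streamlines) is the probability that a
#' retained streamline visits the voxel.
#'
#' @slot counts non-negative volume of per-voxel visitation counts.
#' @slot nGenerated,nRetained integer streamline totals.
#' @slot normalized volume in `[0, 1]`; all-zero when nothing was retained.
#' @slot protocolName character(1).
#' @slot voxelSize numeric(1) mm.
#' @export
setClass("Tractogram", representation(
  counts = "array", nGenerated = "integer", nRetained = "integer",
  normalized = "array", protocolName = "character", voxelSize = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@nRetained > object@nGenerated) msg <- c(msg, "nRetained must be <= nGenerated")
  if (max(object@counts) > object@nRetained && object@nRetained > 0)
    msg <- c(msg, "counts cannot exceed nRetained")
  if (object@nRetained > 0 &&
      max(abs(object@normalized - object@counts / object@nRetained)) > 1e-12)
    msg <- c(msg, "normalized must equal counts / nRetained")
  if (length(msg)) msg else TRUE
})

#' Cluster solution
#'
#' A k-means parcellation of a white-matter ROI: the ROI voxels and their
#' cluster labels, canonically relabeled by descending cluster size (ties by
#' lowest member voxel index).
#'
#' @slot voxels `n x 3` integer matrix of ROI voxel coordinates.
#' @slot labels integer per-voxel cluster id in `1..k`.
#' @slot k integer(1) cluster count.
#' @slot subjectId character(1).
#' @slot dim integer(3) grid shape the voxels live on.
#' @export
setClass("ClusterSolution", representation(
  voxels = "matrix", labels = "integer", k = "integer",
  subjectId = "character", dim = "integer"
), validity = function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@voxels))
    msg <- c(msg, "labels must match the number of ROI voxels")
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(unique(object@labels)) != object@k)
    msg <- c(msg, "every cluster must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Tract mask set
#'
#' Seed (middle position) and anterior/posterior waypoint masks per tract,
#' derived from cluster-probability maps.  All masks contain the same number
#' of voxels and masks of different tracts are pairwise disjoint.
#'
#' @slot masks nested list `masks[[tract]][[position]]` of logical volumes
#'   with positions `"anterior"`, `"middle"`, `"posterior"`.
#' @slot nVoxelsPerMask integer(1).
#' @export
setClass("TractMaskSet", representation(
  masks = "list", nVoxelsPerMask = "integer"
), validity = function(object) {
  msg <- character()
  for (tr in names(object@masks)) for (pos in names(object@masks[[tr]])) {
    if (sum(object@masks[[tr]][[pos]]) != object@nVoxelsPerMask)
      msg <- c(msg, sprintf("mask %s/%s has the wrong voxel count", tr, pos))
  }
  trs <- names(object@masks)
  if (length(trs) > 1L) for (pos in names(object@masks[[1L]])) {
    acc <- Reduce(`+`, lapply(trs, function(tr) object@masks[[tr]][[pos]]))
    if (any(acc > 1)) msg <- c(msg, sprintf("masks overlap across tracts at position %s", pos))
  }
  if (length(msg)) msg else TRUE
})

#' Vertexwise connectivity matrix
#'
#' Visitation counts of unconstrained tractography launched from the
#' white-matter voxel adjacent to each surface vertex, one row per vertex,
#' one column per brain voxel.
#'
#' @slot matrix sparse `nv x nvox` non-negative matrix.
#' @slot surface the [SurfaceMesh-class] the rows refer to.
#' @slot params the [TrackingParams-class] used.
#' @export
setClass("VertexConnectivity", representation(
  matrix = "Matrix", surface = "SurfaceMesh", params = "TrackingParams"
), validity = function(object) {
  if (nrow(object@matrix) != nrow(object@surface@vertices))
    "row count must equal the surface vertex count" else TRUE
})

#' Connectivity blueprint
#'
#' Vertex-by-tract matrix whose rows are connectivity fingerprints: the
#' probability that each vertex is reached by each named tract.  Rows are
#' normalized to sum 1; vertices never reached by any tract keep an all-zero
#' row and are flagged so divergence computations can exclude them.
#'
#' @slot matrix `nv x T` matrix, rows sum to 1 or are identically 0.
#' @slot raw the unnormalized vertex-by-tract product, kept for surface
#'   projections (display).
#' @slot tractNames character(T).
#' @slot vertexIds integer row identifiers (surface vertex indices).
#' @slot zeroRows logical flag per row.
#' @export
setClass("Blueprint", representation(
  matrix = "matrix", raw = "matrix", tractNames = "character",
  vertexIds = "integer", zeroRows = "logical"
), validity = function(object) {
  msg <- character()
  if (ncol(object@matrix) != length(object@tractNames))
    msg <- c(msg, "tractNames must match the column count")
  if (length(object@vertexIds) != nrow(object@matrix))
    msg <- c(msg, "vertexIds must match the row count")
  if (any(object@matrix < 0)) msg <- c(msg, "entries must be non-negative")
  rs <- rowSums(object@matrix)
  ok <- abs(rs - 1) <= 1e-9 | rs == 0
  if (!all(ok)) msg <- c(msg, "rows must sum to 1 (1e-9) or be identically 0")
  if (length(msg)) msg else TRUE
})

#' Minimum-divergence map
#'
#' For each defined vertex of one blueprint, the minimum Kullback-Leibler
#' divergence to any defined vertex of the other blueprint, together with the
#' identity of that best-matching vertex.
#'
#' @slot minKl numeric per-vertex minimum KL (nats); `NA` where undefined
#'   (all-zero fingerprints).
#' @slot bestMatch integer vertex id in the other blueprint; `NA` where
#'   undefined.
#' @slot vertexIds integer vertex ids of this blueprint's rows.
#' @slot direction character(1), e.g. `"A->B"`.
#' @export
setClass("DivergenceMap", representation(
  minKl = "numeric", bestMatch = "integer", vertexIds = "integer",
  direction = "character"
), validity = function(object) {
  msg <- character()
  if (any(object@minKl < 0, na.rm = TRUE)) msg <- c(msg, "minKl must be non-negative")
  if (length(object@bestMatch) != length(object@minKl))
    msg <- c(msg, "bestMatch must match minKl length")
  if (length(msg)) msg else TRUE
})
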