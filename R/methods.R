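# Accessors and show methods.

#' @describeIn Blueprint-class tract names of a blueprint.
#' @param x,object a package object.
#' @export
setGeneric("tractNames", function(x) standardGeneric("tractNames"))
#' @rdname Blueprint-class
#' @export
setMethod("tractNames", "Blueprint", function(x) x@tractNames)

#' @describeIn Blueprint-class one vertex's connectivity fingerprint.
#' @param vertex vertex id.
#' @export
fingerprint <- function(x, vertex) {
  i <- match(vertex, x@vertexIds)
  if (is.na(i)) .stopf("vertex %s not in blueprint", vertex)
  setNames(x@matrix[i, ], x@tractNames)
}

#' @describeIn Tractogram-class per-voxel visitation counts.
#' @export
setGeneric("countsVolume", function(x) standardGeneric("countsVolume"))
#' @rdname Tractogram-class
#' @export
setMethod("countsVolume", "Tractogram", function(x) x@counts)

#' @describeIn Tractogram-class normalized visitation map.
#' @export
setGeneric("normalizedVolume", function(x) standardGeneric("normalizedVolume"))
#' @rdname Tractogram-class
#' @export
setMethod("normalizedVolume", "Tractogram", function(x) x@normalized)

#' @describeIn Tractogram-class retained / generated streamline counts.
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))
#' @rdname Tractogram-class
#' @export
setMethod("nRetained", "Tractogram", function(x) x@nRetained)

#' @describeIn SpeciesPhantom-class bundle label volume.
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))
#' @rdname SpeciesPhantom-class
#' @export
setMethod("labelVolume", "SpeciesPhantom", function(x) x@bundleLabels)

#' @describeIn DivergenceMap-class per-vertex minimum divergence.
#' @export
setGeneric("minKl", function(x) standardGeneric("minKl"))
#' @rdname DivergenceMap-class
#' @export
setMethod("minKl", "DivergenceMap", function(x) setNames(x@minKl, x@vertexIds))

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %s grid, %.3g mm voxels, %d orientation(s)/voxel\n",
              paste(object@dim, collapse = "x"), object@voxelSize,
              dim(object@orientations)[2L]))
  cat(sprintf("  dispersion %.1f deg; %d isotropic background voxels\n",
              object@dispersionDeg, sum(object@isotropic)))
})

setMethod("show", "SpeciesPhantom", function(object) {
  cat(sprintf("SpeciesPhantom: %s grid; bundles: %s\n",
              paste(object@field@dim, collapse = "x"),
              paste(object@labelTable$label, collapse = ", ")))
  cat(sprintf("  %d labeled voxels; surface with %d vertices (%d labeled)\n",
              sum(object@bundleLabels > 0), nrow(object@surface@vertices),
              sum(object@vertexTruth > 0)))
})

setMethod("show", "Tractogram", function(object) {
  cat(sprintf("Tractogram '%s': %d/%d streamlines retained; %d voxels visited\n",
              object@protocolName, object@nRetained, object@nGenerated,
              sum(object@counts > 0)))
})

setMethod("show", "Blueprint", function(object) {
  cat(sprintf("Blueprint: %d vertices x %d tracts (%s); %d zero fingerprints\n",
              nrow(object@matrix), length(object@tractNames),
              paste(object@tractNames, collapse = ", "), sum(object@zeroRows)))
})

setMethod("show", "DivergenceMap", function(object) {
  def <- !is.na(object@minKl)
  cat(sprintf("DivergenceMap (%s): %d/%d defined vertices; median min-KL %.4g nats\n",
              object@direction, sum(def), length(def),
              stats::median(object@minKl[def])))
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution (%s): %d voxels in %d clusters (sizes %s)\n",
              object@subjectId, length(object@labels), object@k,
              paste(tabulate(object@labels, object@k), collapse = "/")))
})

setMethod("show", "TractProtocol", function(object) {
  cat(sprintf("TractProtocol '%s': %d seed voxels, %d waypoint(s), %d exclusion(s), %s mode\n",
              object@name, sum(object@seedMask), length(object@waypointMasks),
              length(object@exclusionMasks), object@params@mode))
})
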