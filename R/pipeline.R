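# End-to-end orchestration: phantom cohorts -> connectivity-based
# parcellation -> mask derivation -> protocol-constrained tract
# reconstruction -> connectivity blueprints -> cross-species divergence,
# with every artifact written to disk and checksummed in a JSON manifest.

#' Tract protocols from a bundle label volume
#'
#' Builds one protocol per bundle from ground-truth labels: the seed is the
#' labeled slab around the middle slice, the anterior and posterior
#' waypoints are labeled slabs at the outer positions, the masks of the
#' other tracts act as exclusions (sibling subcomponents of a split bundle
#' are not used as exclusions for each other), and gray matter terminates
#' without deleting.
#'
#' @param phantom a [SpeciesPhantom-class].
#' @param params a [TrackingParams-class]; each protocol gets `seed + i`.
#' @param positions named integer vector with slice indices `anterior`,
#'   `middle`, `posterior` along y.
#' @param nSlices slab thickness per position.
#' @return Named list of [TractProtocol-class].
#' @export
bundleProtocols <- function(phantom, params,
                            positions = c(anterior = 8L, middle = 19L, posterior = 30L),
                            nSlices = 3L) {
  labels <- phantom@bundleLabels
  d <- dim(labels)
  tab <- phantom@labelTable
  slab <- function(center) {
    half <- (nSlices - 1L) %/% 2L
    ys <- (center - half):(center - half + nSlices - 1L)
    ys[ys >= 1L & ys <= d[2L]]
  }
  posMask <- function(id, center) {
    m <- array(FALSE, d)
    ys <- slab(center)
    m[, ys, ] <- labels[, ys, ] == id
    m
  }
  out <- list()
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    seed <- posMask(id, positions[["middle"]])
    wps <- list(anterior = posMask(id, positions[["anterior"]]),
                posterior = posMask(id, positions[["posterior"]]))
    others <- tab$id[tab$id != id & tab$parent != tab$parent[i]]
    excl <- lapply(others, function(oid) {
      posMask(oid, positions[["middle"]]) |
        posMask(oid, positions[["anterior"]]) |
        posMask(oid, positions[["posterior"]])
    })
    p <- params
    p@seed <- params@seed + as.integer(i)
    out[[tab$label[i]]] <- tractProtocol(tab$label[i], seed, wps, excl,
                                         terminationMask = phantom@gmMask,
                                         params = p)
  }
  out
}

#' Tract protocols from a derived mask set
#'
#' As [bundleProtocols()], but seeds and waypoints come from a
#' [TractMaskSet-class] produced by the parcellation stage.
#'
#' @param maskSet a [TractMaskSet-class].
#' @param gmMask termination volume.
#' @param params a [TrackingParams-class].
#' @param siblings optional named list: for each tract, sibling tracts that
#'   must not act as exclusions (subcomponents of the same bundle).
#' @return Named list of [TractProtocol-class].
#' @export
protocolsFromMaskSet <- function(maskSet, gmMask, params, siblings = list()) {
  tracts <- names(maskSet@masks)
  out <- list()
  for (i in seq_along(tracts)) {
    tr <- tracts[i]
    m <- maskSet@masks[[tr]]
    skip <- c(tr, siblings[[tr]])
    excl <- lapply(setdiff(tracts, skip), function(ot)
      maskSet@masks[[ot]]$middle | maskSet@masks[[ot]]$anterior |
        maskSet@masks[[ot]]$posterior)
    p <- params
    p@seed <- params@seed + as.integer(i)
    out[[tr]] <- tractProtocol(tr, m$middle,
                               list(anterior = m$anterior, posterior = m$posterior),
                               excl, terminationMask = gmMask, params = p)
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every setting of a two-species comparison run.  The defaults are
#' the package's canonical demonstration: a monkey-like phantom with three
#' straight longitudinal bundles against a hominid-like phantom whose
#' inferior bundle is split and which carries an additional curved dorsal
#' (arcuate-like) bundle.
#'
#' @param specA,specB [PhantomSpec-class] or a layout name accepted by
#'   [demoPhantomSpec()].
#' @param nSubjects subjects per species.
#' @param roiPositions named slice indices (`anterior`, `middle`,
#'   `posterior`).
#' @param kA,kB clusters per ROI for each species (`NULL`: the species'
#'   bundle count).
#' @param roiSamples,trackSamples,vertexSamples streamlines per seed for the
#'   parcellation, tract-reconstruction and blueprint stages.
#' @param maskVoxels voxels per derived mask.
#' @param seed global seed; every stage derives its stream from it.
#' @return A named list (class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(specA = "three-straight", specB = "with-arcuate",
                           nSubjects = 2L,
                           roiPositions = c(anterior = 8L, middle = 19L, posterior = 30L),
                           kA = NULL, kB = NULL, roiSamples = 50L,
                           trackSamples = 100L, vertexSamples = 50L,
                           maskVoxels = 12L, seed = 1L) {
  if (is.character(specA)) specA <- demoPhantomSpec(specA, seed = seed)
  if (is.character(specB)) specB <- demoPhantomSpec(specB, seed = seed + 1000L)
  structure(list(specA = specA, specB = specB, nSubjects = as.integer(nSubjects),
                 roiPositions = roiPositions, kA = kA, kB = kB,
                 roiSamples = as.integer(roiSamples),
                 trackSamples = as.integer(trackSamples),
                 vertexSamples = as.integer(vertexSamples),
                 maskVoxels = as.integer(maskVoxels), seed = as.integer(seed)),
            class = "pipelineConfig")
}

# One species through phantom -> parcellation -> masks -> tracts ->
# vertex connectivity; returns everything downstream stages need.
.runSpecies <- function(spec, config, speciesTag, seedOffset) {
  cohort <- generateCohort(spec, config$nSubjects)
  ref <- cohort[[1L]]
  d <- ref@field@dim
  k <- nrow(ref@labelTable)
  positions <- config$roiPositions

  solutions <- list(); assignments <- list()
  for (pos in names(positions)) {
    solutions[[pos]] <- list(); assignments[[pos]] <- list()
  }
  for (s in seq_along(cohort)) {
    ph <- cohort[[s]]
    include <- ph@bundleLabels > 0L
    for (pos in names(positions)) {
      roi <- roiSpec(positions[[pos]], include)
      params <- trackingParams(nSamples = config$roiSamples, maxSteps = 200L,
                               seed = config$seed + seedOffset + s * 10L +
                                 match(pos, names(positions)))
      conn <- roiConnectivityMatrix(roi, ph@field, params, ph@gmMask)
      sim <- similarityMatrix(conn)
      sol <- clusterRoi(sim, k, seed = config$seed + seedOffset + s,
                        voxels = roiVoxels(roi), dim = d,
                        subjectId = sprintf("%s%02d", speciesTag, s))
      solutions[[pos]][[s]] <- sol
      assignments[[pos]][[s]] <- assignClustersToTracts(sol, ph@bundleLabels)
    }
  }
  probMaps <- lapply(names(positions), function(pos)
    probabilityMaps(solutions[[pos]], assignments[[pos]],
                    tractIds = ref@labelTable$id))
  names(probMaps) <- names(positions)
  for (pos in names(positions))
    names(probMaps[[pos]]) <- ref@labelTable$label[
      match(as.integer(names(probMaps[[pos]])), ref@labelTable$id)]
  maskSet <- deriveMasks(probMaps, config$maskVoxels)

  # siblings: subcomponents sharing a parent are not exclusions for each other
  sib <- split(ref@labelTable$label, ref@labelTable$parent)
  siblings <- list()
  for (grp in sib) if (length(grp) > 1L)
    for (g in grp) siblings[[g]] <- setdiff(grp, g)

  trackPar <- trackingParams(nSamples = config$trackSamples, maxSteps = 200L,
                             seed = config$seed + seedOffset + 500L)
  protocols <- protocolsFromMaskSet(maskSet, ref@gmMask, trackPar, siblings)
  tracts <- list()
  for (tr in names(protocols)) {
    per <- lapply(seq_along(cohort), function(s) {
      p <- protocols[[tr]]
      p@params@seed <- protocols[[tr]]@params@seed + s * 1000L
      runTractography(p, cohort[[s]]@field)
    })
    tracts[[tr]] <- averageTractograms(per)
  }

  vcs <- lapply(seq_along(cohort), function(s) {
    vp <- trackingParams(nSamples = config$vertexSamples, maxSteps = 200L,
                         seed = config$seed + seedOffset + 900L + s)
    vertexConnectivity(cohort[[s]]@surface, cohort[[s]]@field, vp,
                       cohort[[s]]@wmMask, cohort[[s]]@gmMask)
  })
  vcAvg <- Reduce(`+`, lapply(vcs, function(v) v@matrix)) / length(vcs)

  truthUnion <- Reduce(`|`, lapply(cohort, function(p) p@vertexTruth > 0L))
  list(cohort = cohort, solutions = solutions, assignments = assignments,
       probMaps = probMaps, maskSet = maskSet, protocols = protocols,
       tracts = tracts, vcAvg = vcAvg, truthUnion = truthUnion, ref = ref)
}

#' Run the full two-species pipeline
#'
#' Executes phantom generation, connectivity-based parcellation, mask
#' derivation, protocol-constrained tract reconstruction, blueprint
#' construction and the cross-species divergence analysis; writes every
#' intermediate artifact under `outDir` together with a JSON manifest of
#' parameters, seeds and file checksums.  Identical configurations
#' reproduce identical artifacts.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  resA <- .runSpecies(config$specA, config, "a", 0L)
  resB <- .runSpecies(config$specB, config, "b", 10000L)

  # Common tract space: shared parents; split children of B are combined
  # into the parent column; tracts present in only one species keep a zero
  # column in the other, so a tract unique to one brain can raise divergence.
  parentsA <- unique(resA$ref@labelTable$parent)
  parentsB <- unique(resB$ref@labelTable$parent)
  common <- union(parentsA, parentsB)
  columnFor <- function(res, parent) {
    kids <- res$ref@labelTable$label[res$ref@labelTable$parent == parent]
    if (!length(kids)) return(numeric(prod(res$ref@field@dim)))
    Reduce(`+`, lapply(kids, function(k) as.vector(res$tracts[[k]])))
  }
  tmA <- do.call(cbind, lapply(common, columnFor, res = resA))
  tmB <- do.call(cbind, lapply(common, columnFor, res = resB))
  colnames(tmA) <- colnames(tmB) <- common

  bpA <- maskBlueprint(buildBlueprint(resA$vcAvg, tmA), resA$truthUnion)
  bpB <- maskBlueprint(buildBlueprint(resB$vcAvg, tmB), resB$truthUnion)
  divAB <- minKlMap(bpA, bpB)
  divBA <- minKlMap(bpB, bpA)

  manifest <- list(
    package = as.character(utils::packageVersion("tractoprint")),
    seed = config$seed, nSubjects = config$nSubjects,
    tracts = as.list(common),
    files = list())

  wv <- function(vol, name, vs) {
    p <- file.path(outDir, name); writeVolume(vol, p, vs); p
  }
  vs <- resA$ref@field@voxelSize
  paths <- character()
  for (tag in c("a", "b")) {
    res <- if (tag == "a") resA else resB
    for (tr in names(res$tracts))
      paths <- c(paths, wv(res$tracts[[tr]], sprintf("tract_%s_%s.nii.gz", tag, tr), vs))
    for (pos in names(res$probMaps)) for (tr in names(res$probMaps[[pos]]))
      paths <- c(paths, wv(res$probMaps[[pos]][[tr]],
                           sprintf("probmap_%s_%s_%s.nii.gz", tag, pos, tr), vs))
    sp <- file.path(outDir, sprintf("surface_%s.surf.gii", tag))
    writeGiftiSurface(res$ref@surface, sp); paths <- c(paths, sp)
  }
  bpPathA <- file.path(outDir, "blueprint_a.tsv"); writeBlueprint(bpA, bpPathA)
  bpPathB <- file.path(outDir, "blueprint_b.tsv"); writeBlueprint(bpB, bpPathB)
  divPath <- file.path(outDir, "divergence.tsv")
  writeTsv(data.frame(vertex = divAB@vertexIds, minKl = divAB@minKl,
                      bestMatch = divAB@bestMatch), divPath)
  divPathBA <- file.path(outDir, "divergence_ba.tsv")
  writeTsv(data.frame(vertex = divBA@vertexIds, minKl = divBA@minKl,
                      bestMatch = divBA@bestMatch), divPathBA)
  kmA <- numeric(nrow(resA$ref@surface@vertices)); kmA[divAB@vertexIds] <- divAB@minKl
  gp <- file.path(outDir, "minkl_a.func.gii"); writeGiftiScalar(kmA, gp)
  paths <- c(paths, bpPathA, bpPathB, divPath, divPathBA, gp)

  manifest$files <- lapply(setNames(paths, basename(paths)),
                           function(p) unname(tools::md5sum(p)))
  manifest$divergence <- list(
    medianMinKlAB = stats::median(divAB@minKl, na.rm = TRUE),
    medianMinKlBA = stats::median(divBA@minKl, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
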