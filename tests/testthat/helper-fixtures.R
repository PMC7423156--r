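# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

phantomA <- function() fixture("phA",
  generatePhantom(demoPhantomSpec("three-straight", seed = 11)))

phantomB <- function() fixture("phB",
  generatePhantom(demoPhantomSpec("with-arcuate", seed = 12)))

phantomSplit <- function() fixture("phS",
  generatePhantom(demoPhantomSpec("split-ilf", seed = 13)))

# blueprint ingredients (vertex connectivity + per-bundle tractograms)
blueprintParts <- function(ph, seedV, seedT, nSamples = 100L) {
  key <- sprintf("bp_%d_%d_%d", seedV, seedT, nSamples)
  fixture(key, {
    vc <- vertexConnectivity(ph@surface, ph@field,
      trackingParams(nSamples = nSamples, maxSteps = 200L, seed = seedV),
      ph@wmMask, ph@gmMask)
    tgs <- lapply(bundleProtocols(ph,
      trackingParams(nSamples = nSamples, maxSteps = 200L, seed = seedT)),
      runTractography, field = ph@field)
    list(vc = vc, tgs = tgs)
  })
}

# tract matrix with split children combined into the parent column and an
# optional zero/filled arcuate column
commonTractMatrix <- function(ph, parts, tracts = c("mdlf", "ifof", "ilf"),
                              arcuate = FALSE) {
  cols <- lapply(tracts, function(tr) {
    kids <- ph@labelTable$label[ph@labelTable$parent == tr]
    if (!length(kids)) return(numeric(prod(ph@field@dim)))
    Reduce(`+`, lapply(kids, function(k) as.vector(parts$tgs[[k]]@normalized)))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- tracts
  if (arcuate) {
    arc <- if ("arcuate" %in% names(parts$tgs))
      as.vector(parts$tgs$arcuate@normalized) else numeric(prod(ph@field@dim))
    m <- cbind(m, arcuate = arc)
  }
  m
}

# tiny uniform grid + single-voxel seed protocol used by tracking tests
smallStraightProtocol <- function(dim = c(20L, 20L, 20L), nSamples = 1L,
                                  maxSteps = 10L, stepLength = 0.5,
                                  mode = "probabilistic", seed = 1L) {
  sm <- array(FALSE, dim)
  sm[5, 10, 10] <- TRUE
  tractProtocol("test", sm,
                params = trackingParams(nSamples = nSamples, maxSteps = maxSteps,
                                        stepLength = stepLength, mode = mode,
                                        seed = seed))
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# all permutations of 1..n (tiny n), for brute-force assignment oracles
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}

.voxFromLin <- function(lin, d) {
  lin0 <- lin - 1L
  cbind(lin0 %% d[1] + 1L, (lin0 %/% d[1]) %% d[2] + 1L,
        lin0 %/% (d[1] * d[2]) + 1L)
}
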