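# Streamline propagation, protocol semantics and tractogram arithmetic.

test_that("a zero-dispersion streamline advances exactly step by step", {
  f <- uniformField(c(20, 20, 20), c(1, 0, 0))
  pr <- smallStraightProtocol(maxSteps = 10, stepLength = 0.5)
  res <- propagateStreamline(f, c(4.5, 9.5, 9.5), pr, initialSign = 1, seed = 42)
  endp <- res$path[nrow(res$path), ]
  expect_equal(sqrt(sum((endp - res$path[1, ])^2)), 5.0, tolerance = 1e-12)
  expect_equal(endp, c(9.5, 9.5, 9.5), tolerance = 1e-12)
  expect_identical(res$status, "max_steps")
})

test_that("the curvature threshold stops a 90-degree turn", {
  # field switches from +x to +z halfway: cosine 0 < 0.2
  d <- c(20L, 20L, 20L)
  f <- uniformField(d, c(1, 0, 0))
  xidx <- ((seq_len(prod(d)) - 1L) %% d[1]) + 1L
  half <- which(xidx > 10L)
  f@orientations[half, 1, ] <- matrix(rep(c(0, 0, 1), each = length(half)), ncol = 3)
  pr <- smallStraightProtocol(maxSteps = 50, stepLength = 0.5)
  res <- propagateStreamline(f, c(4.5, 9.5, 9.5), pr, initialSign = 1, seed = 1)
  expect_identical(res$status, "curvature")
  # it stopped at the boundary, never moving in z
  expect_true(all(abs(res$path[, 3] - 9.5) < 1e-9))
  expect_lt(max(res$path[, 1]), 11)
})

test_that("exclusion deletes and termination stops without deleting", {
  d <- c(20L, 20L, 20L)
  f <- uniformField(d, c(1, 0, 0))
  ex <- array(FALSE, d); ex[15, , ] <- TRUE
  tm <- array(FALSE, d); tm[12, , ] <- TRUE
  sm <- array(FALSE, d); sm[5, 10, 10] <- TRUE
  p <- trackingParams(nSamples = 4, maxSteps = 100, stepLength = 0.5, seed = 2)

  # termination first: streamline kept, stops at slab
  prT <- tractProtocol("t", sm, terminationMask = tm, params = p)
  tg <- runTractography(prT, f)
  expect_identical(tg@nRetained, tg@nGenerated)
  expect_equal(sum(tg@counts[13:20, , ]), 0)

  # exclusion: +x streamlines die at the slab and are discarded entirely
  prE <- tractProtocol("e", sm, exclusionMasks = list(ex), params = p)
  tgE <- runTractography(prE, f)
  expect_identical(as.integer(tgE@nGenerated - tgE@nRetained), 2L)  # the +x half
  expect_equal(sum(tgE@counts[6:20, , ]), 0)  # their whole paths removed
})

test_that("waypoint retention uses OR logic across masks", {
  d <- c(20L, 20L, 20L)
  f <- uniformField(d, c(1, 0, 0))
  sm <- array(FALSE, d); sm[10, 10, 10] <- TRUE
  wpA <- array(FALSE, d); wpA[15, , ] <- TRUE   # +x direction only
  wpB <- array(FALSE, d); wpB[5, , ] <- TRUE    # -x direction only
  p <- trackingParams(nSamples = 10, maxSteps = 100, stepLength = 0.5, seed = 3)
  tg <- runTractography(tractProtocol("w", sm, list(wpA, wpB), params = p), f)
  expect_identical(tg@nRetained, tg@nGenerated)  # every sign crosses one
  tgA <- runTractography(tractProtocol("wa", sm, list(wpA), params = p), f)
  expect_identical(as.integer(tgA@nRetained), 5L)  # only the +x half

  # waypoint equal to the seed: trivially all retained
  tgS <- runTractography(tractProtocol("ws", sm, list(sm), params = p), f)
  expect_identical(tgS@nRetained, tgS@nGenerated)
})

test_that("normalization divides counts by retained streamlines", {
  ph <- phantomA()
  pr <- bundleProtocols(ph, trackingParams(nSamples = 50, maxSteps = 200, seed = 9))$mdlf
  tg <- runTractography(pr, ph@field)
  expect_true(tg@nRetained > 0)
  expect_equal(tg@normalized, tg@counts / tg@nRetained)
  expect_lte(max(tg@normalized), 1)
  expect_gte(min(tg@normalized), 0)
  # per-streamline per-voxel increment <= 1 implies this bound
  expect_lte(max(tg@counts), tg@nRetained)
  expect_lte(sum(tg@counts), tg@nRetained * pr@params@maxSteps)
})

test_that("sampleOrientation respects sign alignment, determinism and dispersion", {
  f <- uniformField(c(16, 16, 16), c(0, 1, 0))
  # antipodal symmetry: previous -y flips the canonical +y
  d <- sampleOrientation(f, c(8, 8, 8), previousDir = c(0, -1, 0))
  expect_equal(d, c(0, -1, 0), tolerance = 1e-12)
  # deterministic mode repeats exactly and consumes no RNG
  d1 <- sampleOrientation(f, c(8, 8, 8), mode = "deterministic")
  d2 <- sampleOrientation(f, c(8, 8, 8), mode = "deterministic")
  expect_identical(d1, d2)
  expect_error(sampleOrientation(f, c(30, 8, 8)), "outside")

  # Monte-Carlo: mean angular deviation matches the folded-normal mean
  fd <- uniformField(c(16, 16, 16), c(0, 1, 0), dispersionDeg = 10)
  set.seed(123)
  n <- 10000
  devs <- vapply(seq_len(n), function(i) {
    v <- sampleOrientation(fd, c(8, 8, 8), previousDir = c(0, 1, 0))
    acos(min(1, sum(v * c(0, 1, 0))))
  }, numeric(1))
  sd <- 10 * pi / 180
  foldedMean <- sd * sqrt(2 / pi)
  se <- stats::sd(devs) / sqrt(n)
  expect_lt(abs(mean(devs) - foldedMean), 3 * se)
})

test_that("averaging and downsampling follow their arithmetic definitions", {
  d <- c(4L, 4L, 4L)
  v1 <- array(0.2, d); v2 <- array(0.4, d)
  expect_equal(averageTractograms(list(v1, v2)), array(0.3, d))
  expect_equal(averageTractograms(list(v1, v1, v1)), v1)
  expect_error(averageTractograms(list(v1, array(1, c(2, 2, 2)))), "differ")

  blk <- array(0, c(2, 2, 2)); blk[2, 2, 2] <- 8
  expect_equal(as.vector(downsampleVolume(blk, 2)), 1.0)
  expect_equal(downsampleVolume(v1, 1), v1)
  expect_equal(as.vector(downsampleVolume(array(7, c(4, 4, 4)), 2)), rep(7, 8))
  expect_error(downsampleVolume(array(0, c(3, 4, 4)), 2), "divide")
})

test_that("log normalization maps to [0,1] and preserves order", {
  v <- array(stats::rexp(64), c(4, 4, 4))
  ln <- logNormalize(v)
  expect_equal(max(ln), 1)
  expect_gte(min(ln), 0)
  expect_identical(order(as.vector(v)), order(as.vector(ln)))
  expect_warning(z <- logNormalize(array(0, c(2, 2, 2))), "all-zero")
  expect_equal(z, array(0, c(2, 2, 2)))
  thr <- thresholdMap(ln, 0.7)
  expect_identical(thr, ln >= 0.7)
})

test_that("overlap fraction counts voxels of the tract of interest", {
  d <- c(4L, 4L, 4L)
  a <- array(FALSE, d); a[1:10] <- TRUE
  b <- array(FALSE, d); b[7:20] <- TRUE
  expect_equal(overlapFraction(a, a), 1.0)
  expect_equal(overlapFraction(a, b), 4 / 10)
  expect_equal(overlapFraction(a, array(FALSE, d)), 0.0)
  expect_error(overlapFraction(array(FALSE, d), a), "empty")
})

test_that("deterministic mode is seed-invariant and agrees with probabilistic tracking", {
  ph <- fixture("phDice", generatePhantom(demoPhantomSpec("three-straight",
                                                          seed = 11, dispersionDeg = 5)))
  pr <- bundleProtocols(ph, trackingParams(nSamples = 100, maxSteps = 200, seed = 9))$mdlf
  tgP <- runTractography(pr, ph@field)
  prD <- pr; prD@params@mode <- "deterministic"
  tgD <- runTractography(prD, ph@field)
  prD2 <- prD; prD2@params@seed <- 12345L
  tgD2 <- runTractography(prD2, ph@field)
  expect_identical(tgD@counts, tgD2@counts)

  a <- thresholdMap(logNormalize(tgP@normalized), 0.5)
  b <- thresholdMap(logNormalize(tgD@normalized), 0.5)
  expect_gte(dice(a, b), 0.7)
})

test_that("retention decisions match the brute-force replay oracle", {
  spec <- phantomSpec(list(bundleSpec("b", cbind(5, 5), radiusVox = 2)),
                      gridShape = c(16, 16, 16), gmThickness = 3,
                      dispersionDeg = 15, seed = 4)
  ph <- generatePhantom(spec)
  m <- function() array(FALSE, ph@field@dim)
  sm <- m(); sm[4:6, 7, 4:6] <- TRUE
  wp1 <- m(); wp1[, 12, ] <- TRUE
  wp2 <- m(); wp2[, 3, ] <- TRUE
  exl <- m(); exl[1:2, , ] <- TRUE
  pr <- tractProtocol("t", sm, list(wp1, wp2), list(exl), ph@gmMask,
                      trackingParams(nSamples = 2, maxSteps = 60,
                                     stepLength = 0.5, seed = 21))
  impl <- runTractography(pr, ph@field)
  orac <- oracleTractography(pr, ph@field)
  expect_identical(as.integer(sum(orac$retained)), impl@nRetained)
  expect_identical(impl@counts, orac$counts)
})
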