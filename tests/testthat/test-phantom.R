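# Synthetic phantom generator: geometry, ground truth, determinism.

test_that("phantom construction places the declared bundles with valid orientations", {
  spec <- demoPhantomSpec("three-straight", seed = 3)
  ph <- generatePhantom(spec)

  labs <- sort(unique(as.vector(ph@bundleLabels)))
  expect_identical(labs, c(0L, 1L, 2L, 3L))
  expect_true(all(ph@bundleLabels[ph@bundleLabels > 0] > 0 & ph@wmMask[ph@bundleLabels > 0]))
  expect_false(any(ph@wmMask & ph@gmMask))

  # every weighted orientation is a unit vector
  oriented <- which(!ph@field@isotropic & ph@field@weights[, 1] > 0)
  o <- ph@field@orientations[oriented, 1, ]
  expect_lt(max(abs(sqrt(rowSums(o^2)) - 1)), 1e-9)

  # label conservation: labeled voxel count equals the sum of per-tube volumes
  perTube <- tabulate(ph@bundleLabels[ph@bundleLabels > 0], 3)
  expect_identical(sum(ph@bundleLabels > 0), sum(perTube))
  expect_true(all(perTube > 0))
})

test_that("zero dispersion gives exact centerline tangents", {
  spec <- demoPhantomSpec("three-straight", seed = 5, dispersionDeg = 0)
  ph <- generatePhantom(spec)
  inside <- which(ph@bundleLabels > 0)
  o <- ph@field@orientations[inside, 1, ]
  # straight bundles run along +y
  expect_equal(o, matrix(rep(c(0, 1, 0), each = length(inside)), ncol = 3),
               tolerance = 1e-12)
})

test_that("generation is a pure function of spec and seed", {
  spec <- demoPhantomSpec("with-arcuate", seed = 7)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(a@field@orientations, b@field@orientations)
  expect_identical(a@bundleLabels, b@bundleLabels)
  expect_identical(a@vertexTruth, b@vertexTruth)
  c <- generatePhantom(demoPhantomSpec("with-arcuate", seed = 8))
  expect_false(identical(a@field@orientations, c@field@orientations))
})

test_that("overlapping tubes with distinct labels raise a named error", {
  bad <- phantomSpec(list(bundleSpec("one", cbind(20, 20)),
                          bundleSpec("two", cbind(22, 20))))
  expect_error(generatePhantom(bad), "overlap.*one.*two")
})

test_that("bundles leaving the grid raise an error", {
  bad <- phantomSpec(list(bundleSpec("edge", cbind(1, 20))))
  expect_error(generatePhantom(bad), "leaves the grid")
})

test_that("surface vertices sit on the gray/white border with truth labels over tubes", {
  ph <- phantomA()
  g <- ph@spec@gridShape
  yB <- (g[2] - ph@spec@gmThickness) * ph@spec@voxelSize
  # all vertices lie exactly on the boundary plane
  expect_true(all(abs(ph@surface@vertices[, 2] - yB) < 1e-9))
  # faces reference valid vertices and the edge graph is connected
  expect_true(max(ph@surface@faces) <= nrow(ph@surface@vertices))
  edges <- rbind(ph@surface@faces[, 1:2], ph@surface@faces[, 2:3])
  gAdj <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                               dims = rep(nrow(ph@surface@vertices), 2))
  gAdj <- gAdj + Matrix::t(gAdj)
  reach <- rep(FALSE, nrow(gAdj)); reach[1] <- TRUE
  for (i in 1:80) reach <- reach | as.vector(gAdj %*% reach) > 0
  expect_true(all(reach))
  # labeled vertices match the tube cross-sections at the plate
  expect_true(all(table(ph@vertexTruth[ph@vertexTruth > 0]) > 5))
})

test_that("cohorts share labels and jitter produces partial bundle overlap", {
  spec <- demoPhantomSpec("three-straight", seed = 21, dispersionDeg = 10,
                          subjectJitterVox = 2)
  cohort <- generateCohort(spec, 4)
  expect_length(cohort, 4)
  invent <- lapply(cohort, function(p) p@labelTable$label)
  for (i in 2:4) expect_identical(invent[[i]], invent[[1]])

  # mean pairwise Dice of corresponding bundle masks is strictly inside (0, 1)
  ds <- c()
  for (i in 1:3) for (j in (i + 1):4) for (id in 1:3) {
    ds <- c(ds, dice(cohort[[i]]@bundleLabels == id, cohort[[j]]@bundleLabels == id))
  }
  expect_gt(mean(ds), 0)
  expect_lt(mean(ds), 1)

  # no jitter, one subject: identical to direct generation
  spec0 <- demoPhantomSpec("three-straight", seed = 21, subjectJitterVox = 0)
  one <- generateCohort(spec0, 1)[[1]]
  direct <- generatePhantom(spec0)
  expect_identical(one@field@orientations, direct@field@orientations)
  expect_identical(one@bundleLabels, direct@bundleLabels)
})

test_that("matched pairs expose the homology correspondence", {
  specA <- demoPhantomSpec("three-straight", seed = 31)
  # identical specs: identity correspondence on labeled vertices
  mp <- matchedPair(specA, specA)
  expect_true(all(mp$correspondence$labelA == mp$correspondence$labelB))
  expect_true(all(mp$correspondence$hasCounterpart))

  # split pair: parent maps onto the union of the children
  specS <- demoPhantomSpec("split-ilf", seed = 31)
  mps <- matchedPair(specA, specS)
  ilfRows <- mps$correspondence[!is.na(mps$correspondence$labelB) &
                                  mps$correspondence$labelB %in% c("ilf_lat", "ilf_med"), ]
  expect_gt(nrow(ilfRows), 0)
  expect_true(all(ilfRows$hasCounterpart[!is.na(ilfRows$labelB)] |
                    is.na(ilfRows$labelA)))
  # the medial child is congruent with the parent: those vertices correspond
  med <- mps$correspondence[!is.na(mps$correspondence$labelA) &
                              mps$correspondence$labelA == "ilf" &
                              !is.na(mps$correspondence$labelB), ]
  expect_true(all(med$labelB %in% c("ilf_lat", "ilf_med")))
  expect_true(all(med$hasCounterpart))

  # arcuate-only vertices in B have no counterpart
  specB <- demoPhantomSpec("with-arcuate", seed = 31)
  mpb <- matchedPair(specA, specB)
  arc <- mpb$correspondence[!is.na(mpb$correspondence$labelB) &
                              mpb$correspondence$labelB == "arcuate" &
                              is.na(mpb$correspondence$labelA), ]
  expect_gt(nrow(arc), 0)
  expect_false(any(arc$hasCounterpart))
})
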