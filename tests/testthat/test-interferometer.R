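test_that("reference stepping curves follow the fringe model exactly", {
  geom <- tinyGeometry(v0 = 0.25)
  scan <- simulateReference(geom, noiselessSettings(nSteps = 8L, 1000),
                            gridShape = c(50, 40))
  ph <- stepPhases(scan)
  expect_length(ph, 8)
  ## per-pixel expectation I0 (1 + v0 cos(phi_k + phi_pix))
  phiPix <- dfpneumo:::flatFieldPhase(c(50, 40))
  for (k in c(1, 4, 7))
    expect_equal(frames(scan)[, , k],
                 1000 * (1 + 0.25 * cos(ph[k] + phiPix)), tolerance = 1e-12)
  ## v0 = 0: no fringes, all frames equal I0
  flat <- simulateReference(tinyGeometry(v0 = 1e-9),
                            noiselessSettings(nSteps = 8L, 1000),
                            gridShape = c(20, 20))
  expect_lt(diff(range(frames(flat))), 1e-5)
  expect_error(acquisitionSettings(nSteps = 2L), "nSteps")
})

test_that("energy bookkeeping: step-mean equals I0 T regardless of D and v0", {
  geom <- tinyGeometry()
  set <- noiselessSettings(8L, 2000)
  ph <- generatePhantom(tinyConfig())
  scan <- simulateScan(ph, geom, set)
  stepMean <- apply(frames(scan), c(1, 2), mean)
  expect_equal(stepMean, 2000 * exp(-attenuationMap(ph)), tolerance = 1e-9)
})

test_that("Poisson noise has counting statistics and seeded reproducibility", {
  geom <- tinyGeometry()
  set <- acquisitionSettings(8L, 1e4, rngSeed = 99L)
  scan <- simulateReference(geom, set, gridShape = c(120, 120))
  ## per-pixel mean over steps: relative sd approx 1/sqrt(8e4) across pixels
  m <- apply(frames(scan), c(1, 2), mean)
  expect_equal(sd(m) / mean(m), 1 / sqrt(8e4), tolerance = 0.05)
  scan2 <- simulateReference(geom, set, gridShape = c(120, 120))
  expect_identical(frames(scan), frames(scan2))
  scan3 <- simulateReference(geom, acquisitionSettings(8L, 1e4, rngSeed = 100L),
                             gridShape = c(120, 120))
  expect_false(identical(frames(scan), frames(scan3)))
})

test_that("motion artifact perturbs only rows crossing the cardiac edge", {
  geom <- tinyGeometry()
  set <- noiselessSettings(8L, 1000)
  ph <- generatePhantom(tinyConfig())
  ref <- simulateReference(geom, set, gridShape = dim(attenuationMap(ph)))
  scan <- simulateScan(ph, geom, set)
  edge <- dfpneumo:::heartEdgeMask(ph)
  expect_identical(addMotionArtifact(scan, edge, 0), scan)
  pert <- addMotionArtifact(scan, edge, 0.05)
  d0 <- darkfield(retrieveRadiographs(scan, ref))
  d1 <- darkfield(retrieveRadiographs(pert, ref))
  diffRows <- which(rowSums(abs(d1 - d0) > 1e-8) > 0)
  expect_true(all(diffRows %in% which(rowSums(edge) > 0)))
  expect_gt(length(diffRows), 0)
  expect_warning(addMotionArtifact(scan, edge, 0.05, exVivo = TRUE),
                 "ex-vivo")
})

test_that("tile gaps collapse modulation inside the strips only", {
  geom <- tinyGeometry()
  set <- noiselessSettings(8L, 1000)
  scan <- simulateReference(geom, set, gridShape = c(60, 30))
  expect_identical(addTileGaps(scan, list()), scan)
  g <- addTileGaps(scan, list(c(20, 25)))
  f <- fitSteppingCurve(frames(g), stepPhases(g))
  v <- f$a1 / f$a0
  expect_true(all(v[20:25, ] < 0.01))
  expect_equal(v[1:19, ], matrix(0.25, 19, 30), tolerance = 1e-9)
  expect_true(all(g@meta$gapMask[20:25, ]))
})
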