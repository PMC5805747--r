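test_that("stepping-curve fit recovers exact sinusoids and degenerate series", {
  ph <- 2 * pi * (0:7) / 8
  f <- fitSteppingCurve(100 * (1 + 0.25 * cos(ph)), ph)
  expect_equal(f$a0, 100)
  expect_equal(f$a1, 25)
  expect_equal(f$phi, 0, tolerance = 1e-12)
  f <- fitSteppingCurve(rep(42, 8), ph)
  expect_equal(f$a0, 42)
  expect_equal(f$a1, 0)
  expect_equal(f$phi, 0)
  f <- fitSteppingCurve(rep(0, 8), ph)
  expect_true(f$bad)
  expect_error(fitSteppingCurve(c(1, 2), c(0, 1)))
})

test_that("least-squares fit matches the brute-force oracle", {
  ph <- 2 * pi * (0:7) / 8
  withr::with_seed(31, {
    for (i in 1:5) {
      y <- 50 + 20 * runif(1) * cos(ph + runif(1, 0, 2 * pi)) + rnorm(8, 0, 3)
      fit <- fitSteppingCurve(y, ph)
      oracle <- bruteForceSinusoidFit(y, ph)
      expect_equal(fit$a0, oracle$a0, tolerance = 1e-6)
      expect_equal(fit$a1, oracle$a1, tolerance = 1e-6)
      expect_equal(fit$phi, oracle$phi, tolerance = 1e-5)
    }
  })
  ## unequally spaced phases are handled by the same normal equations
  phU <- c(0.1, 0.9, 2.2, 3.0, 4.4, 5.9)
  y <- 10 + 3 * cos(phU + 1.2)
  fit <- fitSteppingCurve(y, phU)
  expect_equal(fit$a0, 10, tolerance = 1e-9)
  expect_equal(fit$a1, 3, tolerance = 1e-9)
  expect_equal(fit$phi, 1.2, tolerance = 1e-9)
})

test_that("noiseless forward simulation and retrieval round-trip T and D", {
  geom <- tinyGeometry()
  set <- noiselessSettings()
  ph <- generatePhantom(tinyConfig())
  ref <- simulateReference(geom, set, gridShape = dim(attenuationMap(ph)))
  pair <- retrieveRadiographs(simulateScan(ph, geom, set), ref)
  expect_lt(max(abs(transmission(pair) - exp(-attenuationMap(ph)))), 1e-10)
  expect_lt(max(abs(darkfield(pair) - exp(-scatterMap(ph)))), 1e-10)
  ## registration contract: no resampling
  expect_identical(dim(transmission(pair)), dim(attenuationMap(ph)))
  ## sample identical to reference retrieves unity images
  pair0 <- retrieveRadiographs(ref, ref)
  expect_lt(max(abs(transmission(pair0) - 1)), 1e-12)
  expect_lt(max(abs(darkfield(pair0) - 1)), 1e-12)
})

test_that("increasing scatter strictly decreases noiseless dark-field", {
  geom <- tinyGeometry()
  set <- noiselessSettings()
  ph <- generatePhantom(tinyConfig(textureLungSd = 0))
  ref <- simulateReference(geom, set, gridShape = dim(attenuationMap(ph)))
  d0 <- darkfield(retrieveRadiographs(simulateScan(ph, geom, set), ref))
  ph2 <- ph
  lung <- regionMask(ph, "left_lung")
  ph2@scatter[lung] <- ph2@scatter[lung] + 0.2
  d1 <- darkfield(retrieveRadiographs(simulateScan(ph2, geom, set), ref))
  expect_true(all(d1[lung] < d0[lung]))
  expect_equal(d1[!lung], d0[!lung])
})

test_that("dark-field retrieval is unbiased to first order under photon noise", {
  ## flat region Monte Carlo at 1e4 photons/step: cohort-mean D within 1 %
  geom <- tinyGeometry()
  tMap <- matrix(0.7, 40, 40); dMap <- matrix(0.8, 40, 40)
  ref <- simulateReference(geom, noiselessSettings(), gridShape = c(40, 40))
  means <- vapply(1:6, function(s) {
    set <- acquisitionSettings(8L, 1e4, rngSeed = 1000 + s)
    scan <- dfpneumo:::.simulateStepping(tMap, dMap, geom, set)
    mean(darkfield(retrieveRadiographs(scan, ref)))
  }, 1)
  expect_equal(mean(means), 0.8, tolerance = 0.01)
})

test_that("retrieval masks pixels without usable reference modulation", {
  geom <- tinyGeometry()
  set <- noiselessSettings(photonsPerStep = 500)
  ref <- simulateReference(geom, set, gridShape = c(150, 60))
  ph <- generatePhantom(phantomConfig(pixelSizeCm = 0.25, rngSeed = 3))
  ref <- simulateReference(geom, set, gridShape = dim(attenuationMap(ph)))
  scan <- addTileGaps(simulateScan(ph, geom, set), list(c(10, 14)))
  pair <- retrieveRadiographs(scan, ref)
  expect_true(all(gapMask(pair)[10:14, ]))
  expect_true(all(is.na(darkfield(pair)[10:14, ])))
  expect_true(all(!is.na(darkfield(pair)[20:30, ])))
  ## phase-grid mismatch is rejected
  bad <- simulateReference(geom, noiselessSettings(nSteps = 6),
                           gridShape = dim(attenuationMap(ph)))
  expect_error(retrieveRadiographs(scan, bad), "phases")
})
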