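test_that("ROI statistics match their definition and a brute-force loop", {
  img <- matrix(7, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[3:5, 4:8] <- TRUE
  s <- roiStats(img, roi)
  expect_equal(s$mu, 7)
  expect_equal(s$sigma, 0)
  expect_equal(s$nPixels, 15)
  two <- matrix(FALSE, 10, 10); two[1, 1:2] <- TRUE
  img[1, 1] <- 0; img[1, 2] <- 2
  s <- roiStats(img, two)
  expect_equal(s$mu, 1)
  expect_equal(s$sigma, sqrt(2))   # sample sd
  withr::with_seed(8, img <- matrix(rnorm(100), 10, 10))
  s <- roiStats(img, roi)
  acc <- c()
  for (i in 1:10) for (j in 1:10) if (roi[i, j]) acc <- c(acc, img[i, j])
  expect_equal(s$mu, mean(acc))
  expect_equal(s$sigma, sd(acc))
  expect_error(roiStats(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("CNR implements the printed formula with its invariances", {
  img <- matrix(0, 6, 6)
  roiL <- matrix(FALSE, 6, 6); roiL[1:3, 1:3] <- TRUE
  roiP <- matrix(FALSE, 6, 6); roiP[4:6, 4:6] <- TRUE
  withr::with_seed(13, {
    img[roiL] <- rnorm(9, 3, 1)
    img[roiP] <- rnorm(9, 1, 1)
  })
  sL <- roiStats(img, roiL); sP <- roiStats(img, roiP)
  expect_equal(cnr(img, roiL, roiP),
               abs(sL$mu - sP$mu) / sqrt(sL$sigma^2 + sP$sigma^2))
  ## symmetry, identical ROIs, affine invariance
  expect_equal(cnr(img, roiL, roiP), cnr(img, roiP, roiL))
  expect_equal(cnr(img, roiL, roiL), 0)
  expect_equal(cnr(3.2 * img - 17, roiL, roiP), cnr(img, roiL, roiP))
  expect_equal(cnr(-0.5 * img + 2, roiL, roiP), cnr(img, roiL, roiP))
  expect_error(cnr(matrix(1, 6, 6), roiL, roiP), "undefined")
  ## worked example: means 3 and 1 with unit sds give 2/sqrt(2)
  ex <- matrix(c(3 + c(-1, 0, 1), 1 + c(-1, 0, 1)), 2, 3, byrow = TRUE)
  expect_equal(cnr(ex, row(ex) == 1, row(ex) == 2), 2 / sqrt(2))
})

test_that("projected area is pixel count times squared pixel size", {
  m <- matrix(FALSE, 120, 120)
  m[1:100, 1:100] <- TRUE
  expect_equal(projectedArea(m, 0.036), 12.96)
  expect_equal(projectedArea(matrix(FALSE, 5, 5), 0.036), 0)
  ## the printed cohort-mean baseline area corresponds to ~48.5k full-res px
  expect_equal(48457 * 0.036^2, 62.8, tolerance = 1e-4)
})

test_that("automatic ROIs respect exclusion rules and registration", {
  p <- inducePneumothorax(generatePhantom(tinyConfig()),
                          pneumothoraxSpec("left", "lateral", airVolumeMl = 400))
  rois <- autoPlaceROIs(p)
  lt <- labelTable(p)
  expect_gt(sum(rois$lung), 20)
  expect_gt(sum(rois$pneumo), 20)
  expect_false(any(rois$lung & rois$pneumo))
  labs <- regionLabels(p)
  expect_true(all(labs[rois$lung] == lt[["left_lung"]]))   # no ribs/heart
  expect_true(all(labs[rois$pneumo] == lt[["pleural_gas"]]))
  expect_identical(dim(rois$lung), dim(attenuationMap(p)))
  expect_error(autoPlaceROIs(generatePhantom(tinyConfig())), "no pleural gas")
})

test_that("dark-field segmentation recovers truth areas and collapse", {
  cfg <- tinyConfig()
  base <- generatePhantom(cfg)
  pneu <- inducePneumothorax(base, pneumothoraxSpec("left", "dorsal",
                                                    collapseFraction = 0.25))
  geom <- tinyGeometry()
  set <- noiselessSettings()
  ref <- simulateReference(geom, set, gridShape = dim(attenuationMap(base)))
  dfB <- darkfield(retrieveRadiographs(simulateScan(base, geom, set), ref))
  dfP <- darkfield(retrieveRadiographs(simulateScan(pneu, geom, set), ref))
  band <- retroAnalysisBand(base, "left")
  mB <- segmentInflatedLung(dfB, band)
  mP <- segmentInflatedLung(dfP, band)
  truthB <- regionMask(base, "retro_diaphragmatic_lung_left")
  ## noiseless truth render: Dice >= 0.95 and area within 5 %
  expect_gte(diceCoefficient(mB, truthB), 0.95)
  aB <- projectedArea(mB, pixelSizeCm(base))
  expect_equal(aB, truthAreas(base)[["retro_diaphragmatic_lung_left"]],
               tolerance = 0.05)
  ## affected side strictly smaller after induction
  expect_lt(sum(mP), sum(mB))
  ## a scatter-free image yields an empty mask with a warning
  ones <- matrix(1, nrow(dfB), ncol(dfB))
  expect_warning(m0 <- segmentInflatedLung(ones, band), "empty")
  expect_equal(sum(m0), 0)
})
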