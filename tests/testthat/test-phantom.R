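test_that("grid is derived from the field of view and pixel size", {
  cfg <- phantomConfig(scale = "full")
  expect_identical(cfg$gridShape, c(889L, 972L))  # 32/0.036, 35/0.036 rounded
  expect_identical(phantomConfig(scale = "half")$gridShape, c(444L, 486L))
  expect_error(generatePhantom(phantomConfig(pixelSizeCm = 0.5)),
               "grid too small")
})

test_that("phantom generation is seed-deterministic with consistent truth", {
  p1 <- generatePhantom(tinyConfig())
  p2 <- generatePhantom(tinyConfig())
  expect_identical(attenuationMap(p1), attenuationMap(p2))
  expect_identical(scatterMap(p1), scatterMap(p2))
  p3 <- generatePhantom(tinyConfig(rngSeed = 12L))
  expect_false(identical(scatterMap(p1), scatterMap(p3)))
  ## truth areas equal mask pixel count times pixel area, exactly
  for (side in c("left", "right")) {
    lab <- sprintf("retro_diaphragmatic_lung_%s", side)
    expect_identical(truthAreas(p1)[[lab]],
                     sum(regionMask(p1, lab)) * pixelSizeCm(p1)^2)
  }
  ## drawn target areas are hit to rasterization accuracy
  expect_equal(truthAreas(p1)[["retro_diaphragmatic_lung_left"]], 62.8,
               tolerance = 0.02)
})

test_that("zero texture leaves only the smooth scatter envelope", {
  p <- generatePhantom(tinyConfig(textureLungSd = 0))
  lung <- regionMask(p, "left_lung")
  s <- scatterMap(p)[lung]
  ## smooth radial envelope: small total variation, no grain
  expect_lt(sd(s), 0.2 * mean(s))
  pt <- generatePhantom(tinyConfig())
  expect_gt(sd(scatterMap(pt)[lung]), sd(s))
  ## scatter vanishes outside lung tissue
  expect_equal(max(scatterMap(p)[regionMask(p, "background")]), 0)
})

test_that("lateral pneumothorax carves a gas band scaling with volume", {
  p <- generatePhantom(tinyConfig())
  same <- inducePneumothorax(p, pneumothoraxSpec("left", "lateral",
                                                 airVolumeMl = 0))
  expect_identical(attenuationMap(same), attenuationMap(p))
  expect_identical(scatterMap(same), scatterMap(p))
  p250 <- inducePneumothorax(p, pneumothoraxSpec("left", "lateral",
                                                 airVolumeMl = 250))
  p500 <- inducePneumothorax(p, pneumothoraxSpec("left", "lateral",
                                                 airVolumeMl = 500))
  g250 <- sum(regionMask(p250, "pleural_gas"))
  g500 <- sum(regionMask(p500, "pleural_gas"))
  expect_gt(g250, 0)
  expect_gt(g500, g250)  # 500 ml band strictly wider than 250 ml
  ## gas has no scatter and reduced attenuation
  gas <- regionMask(p500, "pleural_gas")
  expect_equal(max(scatterMap(p500)[gas]), 0)
  expect_true(all(attenuationMap(p500)[gas] < attenuationMap(p)[gas]))
  ## input untouched; re-induction on a non-baseline phantom is rejected
  expect_identical(phantomState(p), "baseline")
  expect_error(inducePneumothorax(p500, pneumothoraxSpec("left", "lateral",
                                                         airVolumeMl = 100)),
               "baseline")
})

test_that("dorsal collapse shrinks only the affected side by the set fraction", {
  p <- generatePhantom(tinyConfig())
  d <- inducePneumothorax(p, pneumothoraxSpec("left", "dorsal",
                                              collapseFraction = 0.205))
  before <- truthAreas(p)[["retro_diaphragmatic_lung_left"]]
  after <- truthAreas(d)[["retro_diaphragmatic_lung_left"]]
  expect_lt(abs((before - after) / before - 0.205), 0.02)
  expect_identical(truthAreas(d)[["retro_diaphragmatic_lung_right"]],
                   truthAreas(p)[["retro_diaphragmatic_lung_right"]])
  ## pneumothorax conservation: no pixel changes on the unaffected side
  right <- col(attenuationMap(p)) > ncol(attenuationMap(p)) / 2
  expect_identical(scatterMap(d)[right], scatterMap(p)[right])
  expect_identical(attenuationMap(d)[right], attenuationMap(p)[right])
})

test_that("cohorts follow the study layout and area distributions", {
  co <- generateCohort(8, cohortSeed = 3, scale = "smoke")
  expect_length(co$animals, 8)
  expect_identical(sum(co$meta$type == "lateral"), 6L)
  expect_identical(sum(co$meta$group == "in_vivo"), 5L)
  expect_true(all(co$meta$type[7:8] == "dorsal"))
  single <- generateCohort(1, cohortSeed = 3, scale = "smoke")
  expect_length(single$animals, 1)
  expect_error(cohortSummary(analyzeCohort(single)@animals), "at least 2")
  ## drawn affected-side baseline areas center on 62.8 cm2 (200 cohorts)
  draws <- unlist(lapply(1:200, function(s)
    generateCohort(2, cohortSeed = 1000 + s, scale = "smoke", nLateral = 2,
                   phantoms = FALSE)$meta$affectedAreaCm2))
  expect_lt(abs(mean(draws) - 62.8), 3 * 7.8 / sqrt(length(draws)))
})
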