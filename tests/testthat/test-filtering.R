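test_that("Gaussian kernel follows the FWHM definition", {
  k <- gaussianKernel1d(3.25)
  expect_equal(sum(k), 1)
  sigma <- 3.25 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 1.380, tolerance = 1e-3)
  ## truncation at 4 sigma: radius 6 -> 13 taps
  expect_length(k, 2 * ceiling(4 * sigma) + 1)
  expect_true(all(diff(k[1:((length(k) + 1) / 2)]) > 0))
})

test_that("gaussianLowpass preserves constants and the image mean", {
  img <- matrix(3.7, 64, 80)
  expect_equal(gaussianLowpass(img), img, tolerance = 1e-12)
  withr::with_seed(4, img <- matrix(rnorm(64 * 80), 64, 80))
  out <- gaussianLowpass(img)
  expect_equal(dim(out), dim(img))
  ## reflection edges keep the global mean to border-effect accuracy
  expect_lt(abs(mean(out) - mean(img)), 5e-3 * sd(img))
})

test_that("Gaussian filter reduces white-noise sd by the kernel norm", {
  withr::with_seed(21, img <- matrix(rnorm(400 * 400), 400, 400))
  out <- gaussianLowpass(img, 3.25)
  k <- gaussianKernel1d(3.25)
  expect_equal(sd(out), sum(k^2), tolerance = 0.03)
  expect_equal(sum(k^2), 0.205, tolerance = 0.01)
})

test_that("binomial3x3 matches its kernel exactly", {
  img <- matrix(2.5, 33, 33)
  expect_equal(binomial3x3(img), img, tolerance = 1e-12)
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  out <- binomial3x3(imp)
  expect_equal(out[6, 6], 0.25)
  expect_equal(out[5, 6], 0.125)
  expect_equal(out[5, 5], 0.0625)
  expect_equal(sum(out), 1)
  ## affine images are fixed points away from the borders
  ramp <- outer(1:30, 1:40, function(i, j) 2 * i - 3 * j + 1)
  out <- binomial3x3(ramp)
  expect_equal(out[2:29, 2:39], ramp[2:29, 2:39], tolerance = 1e-12)
})

test_that("noise equivalence factor reproduces the dose-increase argument", {
  f <- noiseEquivalenceFactor(3.25)
  ## independent oracle: measured variance reduction on simulated white noise
  withr::with_seed(9, img <- matrix(rnorm(500 * 500), 500, 500))
  measured <- var(as.vector(img)) / var(as.vector(gaussianLowpass(img, 3.25)))
  expect_equal(f, measured, tolerance = 0.05)
  expect_equal(f, 23.9, tolerance = 0.01)
  ## identity limit and monotonicity
  expect_lt(noiseEquivalenceFactor(0.1), 1.05)
  ff <- vapply(c(0.5, 1, 2, 3.25, 5, 8), noiseEquivalenceFactor, 1)
  expect_true(all(diff(ff) > 0))
})

test_that("tile-gap filter is display-only and local", {
  withr::with_seed(2, img <- matrix(runif(90 * 90), 90, 90))
  empty <- matrix(FALSE, 90, 90)
  expect_identical(tileGapFilter(img, empty), img)
  strip <- empty; strip[40:46, ] <- TRUE
  out <- tileGapFilter(img, strip)
  expect_true(isTRUE(attr(out, "displayGrade")))
  changed <- which(out != img, arr.ind = TRUE)
  expect_true(all(changed[, 1] >= 37 & changed[, 1] <= 49))
  roi <- empty; roi[10:20, 10:20] <- TRUE
  expect_error(roiStats(out, roi), "display-grade")
  expect_error(segmentInflatedLung(out, list(rows = c(5, 60), cols = c(5, 60))),
               "display-grade")
})
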