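## Small shared fixtures; everything is generated in code at test time.

## coarse phantom for fast structural tests (160 x 175 px at 2 mm pixels)
tinyConfig <- function(rngSeed = 11L, ...) {
  phantomConfig(pixelSizeCm = 0.2, rngSeed = rngSeed, ...)
}

tinyGeometry <- function(v0 = 0.25) scannerGeometry(v0 = v0)

noiselessSettings <- function(nSteps = 8L, photonsPerStep = 1000) {
  acquisitionSettings(nSteps = nSteps, photonsPerStep = photonsPerStep,
                      poissonNoise = FALSE)
}

## brute-force oracle for the stepping-curve fit: dense grid search refined
## by optim, independent of the linear least-squares path
bruteForceSinusoidFit <- function(y, phases) {
  sse <- function(p) sum((y - (p[1] + p[2] * cos(phases + p[3])))^2)
  best <- NULL
  for (phi in seq(0, 2 * pi, length.out = 73)) {
    for (a1 in seq(0, 2 * diff(range(y)) + 1e-9, length.out = 41)) {
      p <- c(mean(y), a1, phi)
      v <- sse(p)
      if (is.null(best) || v < best$v) best <- list(p = p, v = v)
    }
  }
  o <- stats::optim(best$p, sse, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  p <- o$par
  if (p[2] < 0) { p[2] <- -p[2]; p[3] <- p[3] + pi }
  p[3] <- atan2(sin(p[3]), cos(p[3]))
  list(a0 = p[1], a1 = p[2], phi = p[3])
}
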