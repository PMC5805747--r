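## Flat-field fringe phase pattern: the residual moire fringes of the
## stepped grating pair are oriented as horizontal lines (orthogonal to the
## scan direction), so the per-pixel offset phase varies with the row only.
flatFieldPhase <- function(gridShape, periodRows = 48) {
  r <- seq_len(gridShape[1]) - 1L
  matrix(2 * pi * r / periodRows, gridShape[1], gridShape[2])
}

stepPhaseGrid <- function(nSteps) seq(0, 2 * pi, length.out = nSteps + 1L)[seq_len(nSteps)]

## Shared stepping-curve forward model. tMap/dMap are the ideal transmission
## and dark-field signal (1 everywhere for a reference scan).
.simulateStepping <- function(tMap, dMap, geometry, settings, seedOffset = 0L,
                              noiselessOverride = NULL) {
  gridShape <- dim(tMap)
  phases <- stepPhaseGrid(settings@nSteps)
  phiPix <- flatFieldPhase(gridShape)
  i0 <- if (is.finite(settings@photonsPerStep)) settings@photonsPerStep else 1
  noisy <- settings@poissonNoise && is.finite(settings@photonsPerStep)
  if (isTRUE(noiselessOverride)) noisy <- FALSE
  fr <- array(0, c(gridShape, settings@nSteps))
  base <- i0 * tMap
  mod <- geometry@v0 * dMap
  for (k in seq_len(settings@nSteps))
    fr[, , k] <- base * (1 + mod * cos(phases[k] + phiPix))
  if (noisy) {
    fr[] <- withSeed(settings@rngSeed + seedOffset,
                     stats::rpois(length(fr), as.vector(fr)))
  }
  new("SteppingScan", frames = fr, phases = phases,
      meta = list(geometry = geometry, settings = settings,
                  noiseless = !noisy, seedOffset = seedOffset,
                  gapMask = NULL))
}

#' Simulate a reference (flat-field) stepping scan
#'
#' Forward model of the sample-free fringe scan: the k-th frame of each
#' pixel has expectation \eqn{I_0 (1 + v_0 \cos(\varphi_k + \varphi_{pix}))}
#' with the flat-field fringe phase oriented in horizontal lines. Poisson
#' counting noise is applied when the settings request it; by the default
#' calibration the reference is noiseless (a well-averaged flat field).
#'
#' @param geometry a \linkS4class{ScannerGeometry}.
#' @param settings an \linkS4class{AcquisitionSettings}.
#' @param gridShape image grid (rows, cols); default derived from the
#'   geometry's field of view and effective pixel.
#' @return A \linkS4class{SteppingScan}.
#' @export
simulateReference <- function(geometry, settings,
                              gridShape = round(geometry@fovObjectCm * 1e4 /
                                                  geometry@effectivePixelUm)) {
  stopifnot(all(gridShape >= 1))
  ones <- matrix(1, gridShape[1], gridShape[2])
  .simulateStepping(ones, ones, geometry, settings, seedOffset = 7777L)
}

#' Simulate a stepping scan of a thorax phantom
#'
#' Forward model with the sample in the beam: per pixel the k-th frame has
#' expectation \eqn{I_0 T (1 + v_0 D \cos(\varphi_k + \varphi_{pix}))} with
#' \eqn{T = e^{-attenuation}} and \eqn{D = e^{-scatter}}. The strongly
#' scattering lung parenchyma (large scatter line integral) reduces the
#' fringe modulation; free pleural gas does not. The same flat-field phase
#' pattern as the paired reference is used. The model is effective and
#' monochromatic: spectral/beam-hardening physics is out of scope, since
#' every reproduced quantity is an ROI statistic of the retrieved images.
#'
#' @param phantom a \linkS4class{ThoraxPhantom}.
#' @param geometry a \linkS4class{ScannerGeometry}.
#' @param settings an \linkS4class{AcquisitionSettings}.
#' @return A \linkS4class{SteppingScan} matching the phantom grid.
#' @export
simulateScan <- function(phantom, geometry, settings) {
  tMap <- exp(-phantom@attenuation)
  dMap <- exp(-phantom@scatter)
  .simulateStepping(tMap, dMap, geometry, settings,
                    seedOffset = if (phantom@state == "baseline") 11L else 13L)
}

#' Add a cardiac-motion artifact to a stepping scan
#'
#' Organs entering or leaving a region while the fringe pattern is scanned
#' over it produce intensity modulations that signal extraction cannot
#' distinguish from fringe modulation; on the prototype these appear as
#' horizontal streaks at the edges of the heart of animals imaged in vivo.
#' The operator adds a step-correlated intensity perturbation to every row
#' intersecting the cardiac edge mask, with a row-dependent phase, so the
#' retrieved dark-field image shows horizontal bands there.
#'
#' @param scan a \linkS4class{SteppingScan}.
#' @param edgeMask logical matrix marking the cardiac edge.
#' @param amplitude relative intensity amplitude of the perturbation
#'   (0 = identity).
#' @param exVivo logical; artifacts are an in-vivo phenomenon, so applying
#'   one to an ex-vivo scan logs a warning (but still applies it).
#' @return The perturbed \linkS4class{SteppingScan}.
#' @export
addMotionArtifact <- function(scan, edgeMask, amplitude, exVivo = FALSE) {
  stopifnot(is.logical(edgeMask), all(dim(edgeMask) == dim(scan@frames)[1:2]))
  if (amplitude == 0) return(scan)
  if (exVivo)
    warning("motion artifact requested for an ex-vivo scan; applying anyway")
  rows <- which(rowSums(edgeMask) > 0)
  if (!length(rows)) return(scan)
  seed <- scan@meta$settings@rngSeed + 331L
  psi <- withSeed(seed, stats::runif(length(rows), 0, 2 * pi))
  ## band envelope: strongest at mask rows, random per-row phase
  for (i in seq_along(rows)) {
    r <- rows[i]
    a0r <- rowMeans(scan@frames[r, , , drop = TRUE])
    for (k in seq_along(scan@phases)) {
      pert <- amplitude * a0r * cos(scan@phases[k] + psi[i])
      scan@frames[r, , k] <- pmax(0, scan@frames[r, , k] + pert)
    }
  }
  scan@meta$motionArtifact <- list(rows = rows, amplitude = amplitude)
  scan
}

#' Mark grating tile-gap strips in a stepping scan
#'
#' The tiled G1/G2 gratings (eight half-tiles each) leave seam strips with
#' essentially no fringe modulation. The operator collapses the modulated
#' part of the stepping curve to near zero inside the given strips and
#' records a gap mask that retrieval propagates.
#'
#' @param scan a \linkS4class{SteppingScan}.
#' @param gapRows list of integer row ranges \code{c(from, to)} (full-width
#'   horizontal strips); empty list is the identity.
#' @param residualVisibility fraction of the modulation surviving in a gap.
#' @return The \linkS4class{SteppingScan} with gap strips and gap mask.
#' @export
addTileGaps <- function(scan, gapRows = list(), residualVisibility = 0.02) {
  if (!length(gapRows)) return(scan)
  d <- dim(scan@frames)
  mask <- matrix(FALSE, d[1], d[2])
  a0 <- apply(scan@frames, c(1, 2), mean)
  for (rng in gapRows) {
    rows <- seq(max(1L, rng[1]), min(d[1], rng[2]))
    mask[rows, ] <- TRUE
    for (k in seq_len(d[3]))
      scan@frames[rows, , k] <- a0[rows, ] +
        residualVisibility * (scan@frames[rows, , k] - a0[rows, ])
  }
  scan@meta$gapMask <- mask
  scan
}
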