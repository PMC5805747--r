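#' Least-squares sinusoid fit of stepping curves
#'
#' Fits \eqn{a_0 + a_1 \cos(\varphi_k + \varphi)} to per-pixel intensity
#' series by linear least squares on the basis
#' \eqn{(1, \cos\varphi_k, \sin\varphi_k)}; \eqn{a_1 \ge 0} by convention
#' (the phase absorbs the sign). For equally spaced phases over one period
#' this equals the discrete-Fourier estimate.
#'
#' @param series numeric vector of length \code{length(phases)}, or an array
#'   (rows, cols, nSteps); the fit is vectorized over pixels.
#' @param phases step phases in radians (>= 3 values).
#' @return For a vector: list \code{(a0, a1, phi, bad)}. For an array:
#'   list of matrices \code{a0}, \code{a1}, \code{phi} and logical
#'   \code{bad} flagging all-zero series.
#' @examples
#' ph <- 2 * pi * (0:7) / 8
#' fitSteppingCurve(100 * (1 + 0.25 * cos(ph)), ph)  # a0 = 100, a1 = 25
#' @export
fitSteppingCurve <- function(series, phases) {
  stopifnot(length(phases) >= 3, all(diff(phases) > 0))
  isVec <- is.null(dim(series))
  if (isVec) {
    stopifnot(length(series) == length(phases))
    y <- matrix(series, nrow = length(phases))
  } else {
    d <- dim(series)
    stopifnot(length(d) == 3, d[3] == length(phases))
    y <- t(matrix(series, nrow = d[1] * d[2]))
  }
  x <- cbind(1, cos(phases), sin(phases))
  beta <- solve(crossprod(x), crossprod(x, y))   # 3 x npix
  a0 <- beta[1, ]
  a1 <- sqrt(beta[2, ]^2 + beta[3, ]^2)
  phi <- atan2(-beta[3, ], beta[2, ])
  ## phase undefined for (numerically) unmodulated series -> 0 by convention
  phi[a1 <= 1e-12 * pmax(abs(a0), 1)] <- 0
  bad <- colSums(y != 0) == 0
  if (isVec)
    return(list(a0 = a0, a1 = a1, phi = phi, bad = bad))
  shape <- d[1:2]
  list(a0 = matrix(a0, shape[1], shape[2]),
       a1 = matrix(a1, shape[1], shape[2]),
       phi = matrix(phi, shape[1], shape[2]),
       bad = matrix(bad, shape[1], shape[2]))
}

#' Retrieve transmission and dark-field images from paired scans
#'
#' Sinusoid fits of the sample and reference stepping curves give the
#' registered radiograph pair: transmission \eqn{T = a_0^s / a_0^r} and
#' dark-field \eqn{D = (a_1^s/a_0^s) / (a_1^r/a_0^r)}, the relative
#' visibility reduction caused by small-angle scatter. The differential
#' phase is computed but not analyzed further. Pixels whose reference
#' carries no usable mean or modulation (tile gaps, dead pixels) are
#' flagged in the gap mask and set to NA. Retrieval never resamples:
#' output grids equal input grids.
#'
#' @param sample,reference \linkS4class{SteppingScan}s on the same grid with
#'   identical step phases.
#' @param clipD dark-field clipping range applied before analysis; photon
#'   noise can push visibility ratios above 1, and the clip keeps ROI
#'   statistics finite without affecting calibrated signal ranges.
#' @return A \linkS4class{RadiographPair}.
#' @export
retrieveRadiographs <- function(sample, reference, clipD = c(0, 1.5)) {
  if (!isTRUE(all.equal(sample@phases, reference@phases)))
    stop("sample and reference step phases differ")
  if (!all(dim(sample@frames) == dim(reference@frames)))
    stop("sample and reference grids differ")
  fs <- fitSteppingCurve(sample@frames, sample@phases)
  fr <- fitSteppingCurve(reference@frames, reference@phases)
  vr <- fr$a1 / fr$a0
  bad <- fr$bad | fs$bad | fr$a0 <= 0 | !is.finite(vr) |
    vr < 0.05 * stats::median(vr[is.finite(vr)])
  if (!is.null(sample@meta$gapMask)) bad <- bad | sample@meta$gapMask
  tr <- fs$a0 / fr$a0
  df <- (fs$a1 / fs$a0) / vr
  df <- pmin(pmax(df, clipD[1]), clipD[2])
  phase <- fs$phi - fr$phi
  tr[bad] <- NA_real_
  df[bad] <- NA_real_
  new("RadiographPair", transmission = tr, darkfield = df, phase = phase,
      gapMask = bad,
      provenance = list(
        sampleSeed = if (!is.null(sample@meta$settings))
          sample@meta$settings@rngSeed,
        noiselessSample = isTRUE(sample@meta$noiseless),
        noiselessReference = isTRUE(reference@meta$noiseless),
        motionArtifact = sample@meta$motionArtifact,
        clipD = clipD))
}
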