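#' Named calibration presets of the simulation pipeline
#'
#' A calibration fixes the free parameters the imaging study does not print
#' but the ROI statistics of the retrieved images depend on: reference
#' visibility and fluence of the acquisition, signal levels and texture of
#' the phantom, motion-artifact amplitude, the segmentation threshold and
#' the quantitative filter. The preset \code{"paper2018"} is frozen so that
#' the default cohort experiment (8 animals, 6 lateral, half-sampling
#' analysis grid) reproduces the published cohort summary statistics; its
#' phantom-side values are the defaults of \code{\link{phantomConfig}} and
#' were finalized by simulation against the printed lung-to-pneumothorax
#' CNRs.
#'
#' @param name preset name (only \code{"paper2018"} is defined), or a named
#'   list of overrides merged recursively into \code{"paper2018"} (an
#'   already-complete calibration list passes through unchanged).
#' @return Named list of calibration parameters.
#' @export
calibrationPreset <- function(name = "paper2018") {
  if (is.list(name)) return(.mergeLists(calibrationPreset("paper2018"), name))
  if (name != "paper2018") stop("unknown calibration preset: ", name)
  list(
    name = "paper2018",
    v0 = 0.25,
    nSteps = 8L,
    photonsPerStep = 9000,
    noisyReference = FALSE,
    motionAmplitude = 0.01,
    filterFwhmPx = 3.25,
    segThresholdFactor = 0.8,
    roiSideCm = 2,
    phantom = list(
      scatterLung = 0.36, scatterRetro = 0.51,
      muBody = 0.916, muLung = 0.152, muHeart = 0.5, muRib = 0.28,
      muAbdomen = 0.6,
      textureLungSd = 0.16, textureLungFwhmPx = 4.2,
      textureTransSd = 0.26, textureTransFwhmPx = 30),
    cohort = list(
      apDiameterMeanCm = 20.2, apDiameterSdCm = 2.3,
      affectedAreaMeanCm2 = 62.8, affectedAreaSdCm2 = 7.8,
      controlAreaMeanCm2 = 57.6, controlAreaSdCm2 = 10.3,
      collapseMean = 0.205, collapseSd = 0.035,
      lateralVolumeRangeMl = c(200, 500),
      dorsalVolumeRangeMl = c(50, 150),
      lungScaleSd = 0.05, scatterLungSd = 0.035))
}
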