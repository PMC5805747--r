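## Region label codes shared by the phantom and the ROI machinery.
.labelTable <- c(background = 0L, left_lung = 1L, right_lung = 2L,
                 pleural_gas = 3L, retro_diaphragmatic_lung_left = 4L,
                 retro_diaphragmatic_lung_right = 5L, ribs = 6L,
                 heart = 7L, abdomen = 8L)

#' ScannerGeometry: grating-interferometer prototype geometry
#'
#' Grating periods, duty cycles, distances, detector sampling and reference
#' fringe visibility of the large-object fringe-scanning chest scanner. The
#' constructor defaults describe the prototype: source grating G0 (period
#' 68.72 um, duty 0.7), reference grating G1 (8.73 um, 0.5), analyzer
#' grating G2 (10 um, 0.5), source-detector distance 2 m, G0-G1 1.60 m,
#' G1-G2 0.25 m, sample table 5.6 cm upstream of G1, true pixel 444 um,
#' effective pixel 360 um, object-plane field of view 32 x 35 cm.
#' Because G2 sits close behind G1 the system analyzes the direct shadow of
#' G1 rather than a Talbot self-image; for the stepping-curve forward model
#' used here the distinction is provenance only.
#'
#' @slot p0Um,p1Um,p2Um grating periods in micrometers.
#' @slot duty0,duty1,duty2 grating duty cycles.
#' @slot sourceDetectorM,dG0G1M,dG1G2M,sampleOffsetUpstreamG1M distances in m.
#' @slot truePixelUm,effectivePixelUm detector and object-plane pixel, um.
#' @slot fovObjectCm object-plane field of view (rows, cols) in cm.
#' @slot v0 reference fringe visibility, in (0, 1); not printed for the
#'   prototype, default 0.25 as part of calibration \code{"paper2018"}.
#' @export
setClass("ScannerGeometry", representation(
  p0Um = "numeric", p1Um = "numeric", p2Um = "numeric",
  duty0 = "numeric", duty1 = "numeric", duty2 = "numeric",
  sourceDetectorM = "numeric", dG0G1M = "numeric", dG1G2M = "numeric",
  sampleOffsetUpstreamG1M = "numeric",
  truePixelUm = "numeric", effectivePixelUm = "numeric",
  fovObjectCm = "numeric", v0 = "numeric"))

setValidity("ScannerGeometry", function(object) {
  lens <- c(object@p0Um, object@p1Um, object@p2Um, object@sourceDetectorM,
            object@dG0G1M, object@dG1G2M, object@sampleOffsetUpstreamG1M,
            object@truePixelUm, object@effectivePixelUm, object@fovObjectCm)
  if (any(lens <= 0)) return("all lengths and periods must be positive")
  if (object@v0 <= 0 || object@v0 >= 1) return("v0 must be in (0, 1)")
  if (object@effectivePixelUm >= object@truePixelUm)
    return("effective pixel must be smaller than true pixel")
  TRUE
})

#' @rdname ScannerGeometry-class
#' @param v0 reference fringe visibility.
#' @return \code{scannerGeometry()} returns the prototype geometry.
#' @examples
#' scannerGeometry()
#' @export
scannerGeometry <- function(v0 = 0.25) {
  new("ScannerGeometry", p0Um = 68.72, p1Um = 8.73, p2Um = 10,
      duty0 = 0.7, duty1 = 0.5, duty2 = 0.5,
      sourceDetectorM = 2, dG0G1M = 1.60, dG1G2M = 0.25,
      sampleOffsetUpstreamG1M = 0.056,
      truePixelUm = 444, effectivePixelUm = 360,
      fovObjectCm = c(32, 35), v0 = v0)
}

#' AcquisitionSettings: fringe-scan sampling and fluence
#'
#' Number of phase samples per pixel over one fringe period, expected photon
#' count per pixel per step (set \code{Inf} for a noiseless expectation
#' image, e.g. a well-averaged flat field), and the RNG seed of the scan.
#'
#' @slot nSteps integer >= 3 (three unknowns per pixel).
#' @slot photonsPerStep expected photons per pixel per step; \code{Inf} (or
#'   \code{poissonNoise = FALSE}) yields noiseless expectation frames.
#' @slot poissonNoise logical: draw Poisson counts around the expectation.
#' @slot rngSeed integer seed for the photon noise.
#' @export
setClass("AcquisitionSettings", representation(
  nSteps = "integer", photonsPerStep = "numeric", poissonNoise = "logical",
  rngSeed = "integer"))

setValidity("AcquisitionSettings", function(object) {
  if (object@nSteps < 3L)
    return("nSteps must be >= 3: the stepping curve has three unknowns")
  if (object@photonsPerStep <= 0) return("photonsPerStep must be positive")
  if (object@poissonNoise && !is.finite(object@photonsPerStep))
    return("Poisson noise requires a finite photonsPerStep")
  TRUE
})

#' @rdname AcquisitionSettings-class
#' @param nSteps,photonsPerStep,poissonNoise,rngSeed see slots.
#' @export
acquisitionSettings <- function(nSteps = 8L, photonsPerStep = 1e4,
                                poissonNoise = is.finite(photonsPerStep),
                                rngSeed = 1L) {
  new("AcquisitionSettings", nSteps = as.integer(nSteps),
      photonsPerStep = photonsPerStep, poissonNoise = poissonNoise,
      rngSeed = as.integer(rngSeed))
}

#' ThoraxPhantom: projected thorax phantom with ground truth
#'
#' Projection (object-plane) phantom of one animal in one state: attenuation
#' and small-angle-scatter line-integral maps, labeled region masks and true
#' projected areas of the retro-diaphragmatic lung per side. The physical
#' contrast the phantom encodes is the one that makes pneumothorax visible
#' in dark-field radiography: alveolar microstructure scatters strongly
#' (large scatter line integral, low dark-field signal D), free pleural gas
#' does not scatter at all.
#'
#' @slot attenuation non-negative matrix, -ln of the ideal transmission.
#' @slot scatter non-negative matrix, -ln of the ideal dark-field signal.
#' @slot labels integer matrix of region codes (see \code{labelTable}).
#' @slot labelTable named integer vector mapping region names to codes.
#' @slot truthAreasCm2 named numeric: true projected retro-diaphragmatic
#'   lung area per side, cm2 (mask pixel count times pixel area).
#' @slot state \code{"baseline"} or \code{"pneumothorax"}.
#' @slot pixelSizeCm object-plane pixel edge in cm.
#' @slot config the \code{phantomConfig()} list used to build the phantom.
#' @slot anatomy internal anatomical parameters (ellipse centers/axes, cm)
#'   reused by pneumothorax induction and automatic ROI placement.
#' @export
setClass("ThoraxPhantom", representation(
  attenuation = "matrix", scatter = "matrix", labels = "matrix",
  labelTable = "integer", truthAreasCm2 = "numeric", state = "character",
  pixelSizeCm = "numeric", config = "list", anatomy = "list"))

setValidity("ThoraxPhantom", function(object) {
  d <- dim(object@attenuation)
  if (!all(dim(object@scatter) == d, dim(object@labels) == d))
    return("attenuation, scatter and labels must share one grid")
  if (any(object@attenuation < 0) || any(object@scatter < 0))
    return("line-integral maps must be non-negative")
  lt <- object@labelTable
  gas <- object@labels == lt[["pleural_gas"]]
  bg <- object@labels == lt[["background"]]
  lung <- object@labels %in% lt[c("left_lung", "right_lung")]
  if (any(lung)) {
    lim <- 0.01 * mean(object@scatter[lung])
    if (any(object@scatter[gas | bg] > lim))
      return("scatter must vanish (< 1% of lung mean) in pleural gas and background")
  }
  for (side in c("left", "right")) {
    lab <- sprintf("retro_diaphragmatic_lung_%s", side)
    a <- sum(object@labels == lt[[lab]]) * object@pixelSizeCm^2
    if (abs(a - object@truthAreasCm2[[lab]]) > 1e-9)
      return(sprintf("truth area for %s does not equal mask count x pixel area", lab))
  }
  if (!object@state %in% c("baseline", "pneumothorax"))
    return("state must be 'baseline' or 'pneumothorax'")
  TRUE
})

#' PneumothoraxSpec: location and size of an induced pneumothorax
#'
#' @slot side \code{"left"} or \code{"right"}.
#' @slot location \code{"lateral"} (pleural gas band at the chest wall,
#'   sized by instilled air volume) or \code{"dorsal"} (air layered over the
#'   lung in the prone animal, collapsing retro-diaphragmatic lung).
#' @slot airVolumeMl instilled air volume, 0-500 ml (lateral sizing).
#' @slot collapseFraction fraction of retro-diaphragmatic projected lung
#'   area lost, in [0, 1) (dorsal sizing).
#' @export
setClass("PneumothoraxSpec", representation(
  side = "character", location = "character",
  airVolumeMl = "numeric", collapseFraction = "numeric"))

setValidity("PneumothoraxSpec", function(object) {
  if (!object@side %in% c("left", "right")) return("side must be left/right")
  if (!object@location %in% c("lateral", "dorsal"))
    return("location must be lateral/dorsal")
  if (object@airVolumeMl < 0 || object@airVolumeMl > 500)
    return("airVolumeMl must be in [0, 500]")
  if (object@collapseFraction < 0 || object@collapseFraction >= 1)
    return("collapseFraction must be in [0, 1)")
  TRUE
})

#' @rdname PneumothoraxSpec-class
#' @param side,location,airVolumeMl,collapseFraction see slots.
#' @export
pneumothoraxSpec <- function(side, location = c("lateral", "dorsal"),
                             airVolumeMl = 0, collapseFraction = 0) {
  new("PneumothoraxSpec", side = side, location = match.arg(location),
      airVolumeMl = airVolumeMl, collapseFraction = collapseFraction)
}

#' SteppingScan: per-pixel intensity series over fringe-scan phases
#'
#' Stack of photon-count frames recorded while the intensity fringe pattern
#' is stepped over each pixel, plus the step phases and provenance.
#'
#' @slot frames numeric array (rows, cols, nSteps) of counts (>= 0).
#' @slot phases step phases in radians, strictly increasing in [0, 2 pi).
#' @slot meta provenance list: geometry, settings, seed, noiseless flag,
#'   gap mask, artifact bookkeeping.
#' @export
setClass("SteppingScan", representation(
  frames = "array", phases = "numeric", meta = "list"))

setValidity("SteppingScan", function(object) {
  if (length(dim(object@frames)) != 3)
    return("frames must be a rows x cols x nSteps array")
  if (dim(object@frames)[3] != length(object@phases))
    return("one phase per frame required")
  if (any(diff(object@phases) <= 0)) return("phases must be strictly increasing")
  if (any(object@frames < 0)) return("counts must be non-negative")
  TRUE
})

#' RadiographPair: registered transmission and dark-field images
#'
#' Result of stepping-curve retrieval on one exposure. Transmission and
#' dark-field are pixel-registered by construction because they come from
#' the same fit; the phase image is computed but not analyzed further.
#'
#' @slot transmission matrix T in (0, 1 + eps].
#' @slot darkfield matrix D in (0, 1 + eps], clipped to [0, 1.5] upstream of
#'   ROI analysis.
#' @slot phase matrix of retrieved differential phases, radians.
#' @slot gapMask logical matrix: pixels where the reference carried no
#'   usable modulation (grating tile gaps, dead pixels).
#' @slot provenance list of seeds, geometry hash and processing flags.
#' @export
setClass("RadiographPair", representation(
  transmission = "matrix", darkfield = "matrix", phase = "matrix",
  gapMask = "matrix", provenance = "list"))

setValidity("RadiographPair", function(object) {
  d <- dim(object@transmission)
  if (!all(dim(object@darkfield) == d, dim(object@phase) == d,
           dim(object@gapMask) == d))
    return("all images of a pair must share one grid (registration contract)")
  ok <- !object@gapMask
  if (any(!is.finite(object@transmission[ok])) ||
      any(!is.finite(object@darkfield[ok])))
    return("images must be finite outside the gap mask")
  TRUE
})

#' CohortResult: per-animal measurements and cohort statistics
#'
#' @slot animals data.frame with one row per animal: group (ex/in vivo),
#'   pneumothorax type and side, CNRs per modality and filter state,
#'   retro-diaphragmatic areas (affected and control side, both states,
#'   measured and truth).
#' @slot summary list of cohort summaries (see \code{\link{cohortSummary}}).
#' @export
setClass("CohortResult", representation(
  animals = "data.frame", summary = "list"))
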