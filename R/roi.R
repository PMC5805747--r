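.checkQuantitative <- function(image) {
  if (isDisplayGrade(image))
    stop("display-grade image (tile-gap filtered): not valid for quantitative analysis")
  invisible(TRUE)
}

#' ROI mean and standard deviation
#'
#' Plain mean and sample standard deviation of the image over a pixel mask.
#' Display-grade (tile-gap-filtered) images are rejected.
#'
#' @param image numeric matrix (quantitative grade).
#' @param roi logical matrix of the same shape; must be non-empty.
#' @return List \code{(mu, sigma, nPixels)}.
#' @export
roiStats <- function(image, roi) {
  .checkQuantitative(image)
  stopifnot(is.matrix(image), is.logical(roi), all(dim(roi) == dim(image)))
  v <- image[roi]
  if (!length(v)) stop("empty ROI")
  if (anyNA(v)) stop("ROI overlaps masked (gap/artifact) pixels")
  list(mu = mean(v), sigma = stats::sd(v), nPixels = length(v))
}

#' Contrast-to-noise ratio between two ROIs
#'
#' The CNR between the lung and pneumothorax (pleural gas) ROIs,
#' \deqn{\mathrm{CNR} = \frac{|\mu_L - \mu_P|}{\sqrt{\sigma_L^2 + \sigma_P^2}},}
#' with ROI means \eqn{\mu} and sample standard deviations \eqn{\sigma}.
#' The standard deviations mix photon noise and anatomical noise
#' (unresolved structure); the CNR is symmetric in the two ROIs and
#' invariant under a common affine rescaling of the image.
#'
#' @param image numeric matrix (quantitative grade).
#' @param roiL,roiP disjoint, non-empty logical masks (lung and
#'   pneumothorax).
#' @return Scalar CNR.
#' @export
cnr <- function(image, roiL, roiP) {
  sL <- roiStats(image, roiL)
  sP <- roiStats(image, roiP)
  den <- sqrt(sL$sigma^2 + sP$sigma^2)
  if (den == 0) stop("CNR undefined: both ROI standard deviations are zero")
  abs(sL$mu - sP$mu) / den
}

#' Automatic ROI placement from phantom truth masks
#'
#' Places the lung and pneumothorax ROIs of the lateral CNR analysis from
#' the phantom's ground-truth labels, mimicking the manual placement rules
#' of the imaging study: the pneumothorax ROI is the pleural gas band
#' (eroded 1 px, central rows only), the lung ROI is a square of the given
#' physical side in the adjacent lung parenchyma, restricted to lung-labeled
#' pixels (which excludes rib shadow and mediastinal/heart structures) and
#' eroded 3 px from the lung boundary. Identical masks are used for the
#' transmission and dark-field images of a pair (they are registered by
#' construction).
#'
#' @param phantom a \linkS4class{ThoraxPhantom} in pneumothorax state with a
#'   pleural gas band.
#' @param roiSideCm side length of the square lung ROI, cm (default 2 cm;
#'   ROI sizes are an assumption of the pipeline, the protocol does not fix
#'   them).
#' @return List of logical masks \code{(lung, pneumo)} plus placement
#'   provenance.
#' @export
autoPlaceROIs <- function(phantom, roiSideCm = 2) {
  lt <- phantom@labelTable
  gas <- phantom@labels == lt[["pleural_gas"]]
  if (!any(gas)) stop("phantom has no pleural gas band (no lateral pneumothorax)")
  px <- phantom@pixelSizeCm
  side <- names(which.max(c(
    left = sum(gas[, seq_len(ncol(gas) %/% 2)]),
    right = sum(gas[, (ncol(gas) %/% 2 + 1):ncol(gas)]))))
  ## pneumothorax ROI: eroded gas band, central 70% of its row range
  gasEr <- EBImage::erode(gas * 1, EBImage::makeBrush(3, "box")) > 0
  rows <- range(which(rowSums(gasEr) > 0))
  pad <- 0.15 * diff(rows)
  keep <- matrix(FALSE, nrow(gas), ncol(gas))
  keep[ceiling(rows[1] + pad):floor(rows[2] - pad), ] <- TRUE
  pneumo <- gasEr & keep
  if (!any(pneumo)) pneumo <- gasEr
  ## lung ROI: square centered at the gas centroid row, displaced medially
  lay <- phantom@anatomy
  dir <- if (side == "left") -1 else 1
  lungLab <- lt[[sprintf("%s_lung", side)]]
  lung <- phantom@labels == lungLab
  ## erode the geometric lung field (3 px margin from the pleural boundary),
  ## then keep lung-labeled pixels only: rib shadow and heart are excluded
  ## without eroding away the inter-rib strips
  g <- coordGrids(dim(lung), px)
  cc0 <- lay$midCol + dir * lay$lung$dc
  body <- ellipseMask(g, lay$body$cr, lay$body$cc, lay$body$a, lay$body$b)
  lungGeom <- ellipseMask(g, lay$lung$cr, cc0, lay$lung$a, lay$lung$b) &
    g$R < lay$diaphragmRow & body
  lungEr <- EBImage::erode(lungGeom * 1, EBImage::makeBrush(7, "box")) > 0 &
    lung
  rCenter <- round(mean(which(rowSums(pneumo) > 0)))
  cCenter <- round(((lay$midCol + dir * (lay$lung$dc + 0.25 * lay$lung$b))) / px)
  h <- max(1L, round(roiSideCm / px / 2))
  rr <- max(1L, rCenter - h):min(nrow(lung), rCenter + h)
  cc <- max(1L, cCenter - h):min(ncol(lung), cCenter + h)
  sq <- matrix(FALSE, nrow(lung), ncol(lung))
  sq[rr, cc] <- TRUE
  lungRoi <- sq & lungEr
  if (sum(lungRoi) < 25) stop("lung ROI placement failed: too few lung pixels")
  list(lung = lungRoi, pneumo = pneumo,
       provenance = list(method = "auto-from-truth-masks", side = side,
                         roiSideCm = roiSideCm))
}

#' Row/column analysis band around the retro-diaphragmatic lung
#'
#' Bounding box of the baseline retro-diaphragmatic truth mask of one side,
#' padded by a physical margin. The band is derived once from the baseline
#' phantom and reused for the pneumothorax state, mirroring an ROI drawn
#' once around the scattering lung.
#'
#' @param phantom baseline \linkS4class{ThoraxPhantom}.
#' @param side \code{"left"} or \code{"right"}.
#' @param padCm margin around the bounding box, cm.
#' @return List \code{(rows, cols)} of index ranges.
#' @export
retroAnalysisBand <- function(phantom, side, padCm = 1.5) {
  lt <- phantom@labelTable
  m <- phantom@labels == lt[[sprintf("retro_diaphragmatic_lung_%s", side)]]
  if (!any(m)) stop("no retro-diaphragmatic lung labeled on side ", side)
  pad <- round(padCm / phantom@pixelSizeCm)
  rr <- range(which(rowSums(m) > 0)) + c(-pad, pad)
  cc <- range(which(colSums(m) > 0)) + c(-pad, pad)
  ## the band never reaches above the diaphragm: the quantity of interest is
  ## lung behind the diaphragm, and the strongly scattering main lung just
  ## above it would otherwise blur into the segmentation
  topLimit <- floor(phantom@anatomy$diaphragmRow / phantom@pixelSizeCm) + 1L
  rr[1] <- max(rr[1], topLimit)
  list(rows = pmax(1L, pmin(nrow(m), rr)), cols = pmax(1L, pmin(ncol(m), cc)))
}

#' Segment inflated (scattering) lung in a dark-field image
#'
#' The scattering lung is directly and exclusively visible in the
#' dark-field image, so inflated lung behind the diaphragm is segmented by
#' thresholding: the image is Gaussian low-pass filtered, restricted to the
#' side's analysis band, thresholded at a fraction of the local
#' gas/background plateau level (strong scatter = low D), morphologically
#' closed, and the largest connected component is kept. Deterministic.
#'
#' @param image quantitative-grade dark-field matrix.
#' @param band analysis band from \code{\link{retroAnalysisBand}}.
#' @param thresholdFactor fraction of the plateau median used as threshold
#'   (default 0.8, frozen in calibration \code{"paper2018"}; this places the
#'   decision boundary at the midpoint of the filter-blurred lung/gas edge,
#'   which keeps the segmented area free of a systematic rim bias).
#' @param filterFwhmPx FWHM of the pre-segmentation low-pass, px.
#' @return Logical mask on the full image grid (with a warning and an empty
#'   mask when no component is found).
#' @export
segmentInflatedLung <- function(image, band, thresholdFactor = 0.8,
                                filterFwhmPx = 3.25) {
  .checkQuantitative(image)
  rr <- seq(band$rows[1], band$rows[2])
  cc <- seq(band$cols[1], band$cols[2])
  ## filter a margin-padded crop only; the kernel support never reaches the
  ## band interior from outside the margin
  mar <- ceiling(4 * filterFwhmPx / (2 * sqrt(2 * log(2)))) + 1L
  rrM <- max(1L, band$rows[1] - mar):min(nrow(image), band$rows[2] + mar)
  ccM <- max(1L, band$cols[1] - mar):min(ncol(image), band$cols[2] + mar)
  smM <- gaussianLowpass(image[rrM, ccM, drop = FALSE], filterFwhmPx)
  sub <- smM[match(rr, rrM), match(cc, ccM)]
  plateau <- sub[!is.na(sub) & sub > 0.9]
  lev <- if (length(plateau) >= 10) stats::median(plateau) else 1
  m <- !is.na(sub) & sub < thresholdFactor * lev
  if (!any(m)) {
    warning("no scattering lung found in the analysis band: empty mask")
    out <- matrix(FALSE, nrow(image), ncol(image))
    return(out)
  }
  m <- EBImage::closing(m * 1, EBImage::makeBrush(5, "disc")) > 0
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  out <- matrix(FALSE, nrow(image), ncol(image))
  out[rr, cc] <- m
  out
}

#' Projected area of a pixel mask in the object plane
#'
#' @param mask logical matrix.
#' @param pixelSizeCm object-plane pixel edge, cm.
#' @return Area in cm2 (pixel count times squared pixel size).
#' @examples
#' projectedArea(matrix(TRUE, 100, 100), 0.036)  # 12.96 cm2
#' @export
projectedArea <- function(mask, pixelSizeCm) {
  stopifnot(pixelSizeCm > 0, is.logical(mask))
  sum(mask) * pixelSizeCm^2
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b logical matrices of one shape.
#' @return 2|A n B| / (|A| + |B|); 1 for identical non-empty masks.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
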