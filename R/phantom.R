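#' Phantom configuration
#'
#' Builds the configuration list for \code{\link{generatePhantom}}: grid and
#' object-plane pixel size, gross anatomy of a stylized porcine thorax in
#' posterior-anterior projection (row 0 is the top/dorsal image edge), and
#' the texture model. The anatomy is a deliberately simple 2-D rendering --
#' elliptical body, two lung fields clipped at the diaphragm, dome of
#' retro-diaphragmatic lung per side, heart, rib bands, abdominal step --
#' because every downstream quantity is an ROI statistic, not a shape
#' measurement.
#'
#' Texture has two components, both correlated Gaussian fields:
#' high-spatial-frequency granularity of the lung scatter signal (alveolar
#' microstructure) and low-frequency structure of the attenuation
#' (unresolved soft tissue). Their amplitudes and correlation lengths, with
#' the fluence and visibility of the acquisition, form the calibration of
#' the whole pipeline (see \code{\link{calibrationPreset}}).
#'
#' @param scale grid scale: \code{"half"} (0.072 cm/px, the default
#'   analysis grid), \code{"full"} (0.036 cm/px, the prototype's effective
#'   pixel) or \code{"smoke"} (0.144 cm/px).
#' @param pixelSizeCm object-plane pixel edge in cm; overrides \code{scale}.
#' @param fovCm field of view (rows, cols) in cm.
#' @param apDiameterCm anterior-posterior thoracic diameter (beam path,
#'   scales the body attenuation mildly).
#' @param bodyMassKg cosmetic only.
#' @param retroAreaCm2 named target projected areas (cm2) of the
#'   retro-diaphragmatic lung, \code{c(left = , right = )}.
#' @param lungScale relative scale of the lung fields.
#' @param scatterLung,scatterRetro scatter line integrals of main and
#'   retro-diaphragmatic lung (dark-field signal e^-scatter).
#' @param muBody,muLung,muHeart,muRib,muAbdomen attenuation line integrals
#'   of the components.
#' @param textureLungSd,textureLungFwhmPx amplitude (scatter-domain sd) and
#'   correlation FWHM (px) of the lung granularity; retro-diaphragmatic
#'   lung carries half the amplitude.
#' @param textureTransSd,textureTransFwhmPx amplitude (attenuation-domain
#'   sd) and correlation FWHM (px) of the low-frequency body structure.
#' @param rngSeed integer seed; fixed seed gives bit-identical phantoms.
#' @return A named list of class \code{"phantomConfig"}.
#' @export
phantomConfig <- function(scale = c("half", "full", "smoke"),
                          pixelSizeCm = NULL,
                          fovCm = c(32, 35),
                          apDiameterCm = 20.2,
                          bodyMassKg = 25.8,
                          retroAreaCm2 = c(left = 62.8, right = 57.6),
                          lungScale = 1,
                          scatterLung = 0.36,
                          scatterRetro = 0.51,
                          muBody = 0.916,
                          muLung = 0.152,
                          muHeart = 0.5,
                          muRib = 0.28,
                          muAbdomen = 0.6,
                          textureLungSd = 0.16,
                          textureLungFwhmPx = 4.2,
                          textureTransSd = 0.26,
                          textureTransFwhmPx = 30,
                          rngSeed = 1L) {
  scale <- match.arg(scale)
  if (is.null(pixelSizeCm))
    pixelSizeCm <- c(half = 0.072, full = 0.036, smoke = 0.144)[[scale]]
  stopifnot(pixelSizeCm > 0, all(fovCm > 0),
            textureLungFwhmPx >= 1, textureTransFwhmPx >= 1,
            all(retroAreaCm2 > 0), c("left", "right") %in% names(retroAreaCm2))
  gridShape <- as.integer(round(fovCm / pixelSizeCm))
  structure(list(
    gridShape = gridShape, pixelSizeCm = pixelSizeCm, fovCm = fovCm,
    apDiameterCm = apDiameterCm, bodyMassKg = bodyMassKg,
    retroAreaCm2 = retroAreaCm2, lungScale = lungScale,
    scatterLung = scatterLung, scatterRetro = scatterRetro,
    muBody = muBody, muLung = muLung, muHeart = muHeart, muRib = muRib,
    muAbdomen = muAbdomen,
    textureLungSd = textureLungSd, textureLungFwhmPx = textureLungFwhmPx,
    textureTransSd = textureTransSd, textureTransFwhmPx = textureTransFwhmPx,
    rngSeed = as.integer(rngSeed)), class = "phantomConfig")
}

## Fixed anatomical layout in cm, derived from the config. Column convention:
## "left" structures sit at lower column indices.
.anatomyLayout <- function(config) {
  fov <- config$fovCm
  midCol <- fov[2] / 2
  ls <- config$lungScale
  lay <- list(
    midCol = midCol,
    body = list(cr = 0.52 * fov[1], cc = midCol,
                a = 0.425 * fov[1],
                b = 0.345 * fov[2] * (1 + 0.5 * (ls - 1))),
    diaphragmRow = 17.6,
    lung = list(cr = 11.4, dc = 6.3 * ls, a = 6.8 * ls, b = 4.6 * ls),
    heart = list(cr = 14.2, cc = midCol + 1.5, a = 3.6, b = 3.2),
    ribs = list(topRow = 4.8, spacing = 1.55, thickness = 0.5, count = 9L),
    retroAspect = 1.15, retroTopGap = 0.15, retroDc = 6.2)
  lay
}

.retroEllipse <- function(lay, side, areaCm2) {
  a <- sqrt(areaCm2 / (lay$retroAspect * pi))
  b <- lay$retroAspect * a
  dir <- if (side == "left") -1 else 1
  list(cr = lay$diaphragmRow + lay$retroTopGap + a,
       cc = lay$midCol + dir * lay$retroDc, a = a, b = b)
}

#' Generate a baseline thorax phantom
#'
#' Renders the stylized anatomy into attenuation and scatter line-integral
#' maps with labeled region masks and ground-truth retro-diaphragmatic
#' areas. The scatter map is a smooth per-lung envelope plus correlated
#' granular texture; the attenuation map carries ribs, heart, the
#' diaphragm/abdomen step and low-frequency correlated structure.
#' Deterministic for a fixed \code{rngSeed}.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return A \linkS4class{ThoraxPhantom} in baseline state.
#' @export
generatePhantom <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  gs <- config$gridShape
  if (any(gs < 128L))
    stop("grid too small to contain the anatomy: need at least 128 px per axis, got ",
         paste(gs, collapse = " x "))
  px <- config$pixelSizeCm
  lay <- .anatomyLayout(config)
  g <- coordGrids(gs, px)

  body <- ellipseMask(g, lay$body$cr, lay$body$cc, lay$body$a, lay$body$b)
  lungMasks <- list()
  envelope <- matrix(0, gs[1], gs[2])
  for (side in c("left", "right")) {
    dir <- if (side == "left") -1 else 1
    cc <- lay$midCol + dir * lay$lung$dc
    rho2 <- ((g$R - lay$lung$cr) / lay$lung$a)^2 +
      ((g$C - cc) / lay$lung$b)^2
    m <- rho2 <= 1 & g$R < lay$diaphragmRow & body
    lungMasks[[side]] <- m
    envelope[m] <- config$scatterLung * (1 - 0.2 * rho2[m])
  }
  retroMasks <- list()
  for (side in c("left", "right")) {
    e <- .retroEllipse(lay, side, config$retroAreaCm2[[side]])
    retroMasks[[side]] <- ellipseMask(g, e$cr, e$cc, e$a, e$b)
  }
  heart <- ellipseMask(g, lay$heart$cr, lay$heart$cc, lay$heart$a, lay$heart$b)
  ribRows <- lay$ribs$topRow + lay$ribs$spacing * (seq_len(lay$ribs$count) - 1L)
  ribs <- matrix(FALSE, gs[1], gs[2])
  for (r0 in ribRows)
    ribs <- ribs | (g$R >= r0 & g$R < r0 + lay$ribs$thickness)
  ribs <- ribs & body & g$R < lay$diaphragmRow
  abdomen <- body & g$R >= lay$diaphragmRow

  tex <- withSeed(config$rngSeed, list(
    lung = correlatedField(gs[1], gs[2], config$textureLungFwhmPx),
    trans = correlatedField(gs[1], gs[2], config$textureTransFwhmPx)))

  anyLung <- lungMasks$left | lungMasks$right
  anyRetro <- retroMasks$left | retroMasks$right
  scatter <- envelope
  scatter[anyRetro] <- config$scatterRetro
  texAmp <- matrix(0, gs[1], gs[2])
  texAmp[anyLung] <- config$textureLungSd
  texAmp[anyRetro] <- 0.5 * config$textureLungSd
  scatter <- scatter + texAmp * tex$lung
  scatter[scatter < 0] <- 0
  scatter[!(anyLung | anyRetro)] <- 0

  muBodyEff <- config$muBody * (1 + 0.3 * (config$apDiameterCm / 20.2 - 1))
  att <- muBodyEff * body +
    config$muLung * (anyLung | anyRetro) +
    config$muHeart * heart +
    config$muRib * ribs +
    config$muAbdomen * abdomen
  att <- att + config$textureTransSd * tex$trans * body
  att[att < 0] <- 0

  labels <- matrix(.labelTable[["background"]], gs[1], gs[2])
  labels[abdomen] <- .labelTable[["abdomen"]]
  labels[retroMasks$left] <- .labelTable[["retro_diaphragmatic_lung_left"]]
  labels[retroMasks$right] <- .labelTable[["retro_diaphragmatic_lung_right"]]
  labels[lungMasks$left] <- .labelTable[["left_lung"]]
  labels[lungMasks$right] <- .labelTable[["right_lung"]]
  labels[heart] <- .labelTable[["heart"]]
  labels[ribs] <- .labelTable[["ribs"]]

  truth <- c(
    retro_diaphragmatic_lung_left =
      sum(labels == .labelTable[["retro_diaphragmatic_lung_left"]]) * px^2,
    retro_diaphragmatic_lung_right =
      sum(labels == .labelTable[["retro_diaphragmatic_lung_right"]]) * px^2)

  new("ThoraxPhantom", attenuation = att, scatter = scatter,
      labels = labels, labelTable = .labelTable, truthAreasCm2 = truth,
      state = "baseline", pixelSizeCm = px, config = unclass(config),
      anatomy = lay)
}

## Apply one pneumothorax spec in place (no state bookkeeping).
.applyPneumothorax <- function(phantom, spec) {
  lt <- phantom@labelTable
  cfg <- phantom@config
  lay <- phantom@anatomy
  g <- coordGrids(dim(phantom@attenuation), phantom@pixelSizeCm)
  dir <- if (spec@side == "left") -1 else 1
  if (spec@location == "lateral") {
    if (spec@airVolumeMl == 0) return(phantom)
    lungLab <- lt[[sprintf("%s_lung", spec@side)]]
    if (!any(phantom@labels == lungLab))
      stop("no ", spec@side, " lung present in the phantom masks")
    cc <- lay$midCol + dir * lay$lung$dc
    b <- lay$lung$b
    ## gap width grows linearly with instilled volume: 500 ml -> 12 mm
    gapCm <- 1.2 * spec@airVolumeMl / 500
    delta <- gapCm / b
    u <- (g$C - cc) / b
    v <- (g$R - lay$lung$cr) / lay$lung$a
    rho2 <- u^2 + v^2
    ## physics: scatter vanishes and lung tissue leaves the whole displaced
    ## band, including pixels shadowed by ribs; labels: only lung-labeled
    ## pixels become pleural gas, so the gas ROI never includes rib shadow
    body <- ellipseMask(g, lay$body$cr, lay$body$cc, lay$body$a, lay$body$b)
    bandGeom <- rho2 <= 1 & rho2 > (1 - delta)^2 & (u * dir) > 0.3 &
      g$R < lay$diaphragmRow & body
    bandGas <- bandGeom & phantom@labels == lungLab
    phantom@labels[bandGas] <- lt[["pleural_gas"]]
    phantom@scatter[bandGeom] <- 0
    phantom@attenuation[bandGeom] <-
      pmax(0, phantom@attenuation[bandGeom] - cfg$muLung)
  } else {
    retroName <- sprintf("retro_diaphragmatic_lung_%s", spec@side)
    retroLab <- lt[[retroName]]
    old <- phantom@labels == retroLab
    if (!any(old))
      stop("no ", spec@side, " retro-diaphragmatic lung in the phantom masks")
    if (spec@collapseFraction > 0) {
      e <- .retroEllipse(lay, spec@side, cfg$retroAreaCm2[[spec@side]])
      s <- sqrt(1 - spec@collapseFraction)
      shrunk <- ellipseMask(g, e$cr - e$a * (1 - s), e$cc, e$a * s, e$b * s)
      lost <- old & !shrunk
      phantom@labels[lost] <- lt[["abdomen"]]
      phantom@scatter[lost] <- 0
      phantom@attenuation[lost] <-
        pmax(0, phantom@attenuation[lost] - cfg$muLung)
      phantom@truthAreasCm2[[retroName]] <-
        sum(phantom@labels == retroLab) * phantom@pixelSizeCm^2
    }
  }
  phantom
}

#' Induce a pneumothorax in a baseline phantom
#'
#' Lateral pneumothoraces insert a band of free pleural gas between the
#' lateral rib cage and the lung, with width growing monotonically (here:
#' linearly, 500 ml to 12 mm) with the instilled air volume; the band has
#' zero scatter (no dark-field signal) and slightly reduced attenuation.
#' Dorsal pneumothoraces model air layered over the lung of the prone
#' animal: the retro-diaphragmatic lung of the affected side shrinks by the
#' given collapse fraction of its projected area, the truth area is
#' rescaled, and the unaffected side is untouched. The input phantom is not
#' modified.
#'
#' @param phantom a baseline \linkS4class{ThoraxPhantom}.
#' @param spec a \linkS4class{PneumothoraxSpec}, or a list of them applied
#'   in sequence (e.g. a lateral gas band plus dorsal collapse in one
#'   animal).
#' @return A new \linkS4class{ThoraxPhantom} in pneumothorax state.
#' @export
inducePneumothorax <- function(phantom, spec) {
  if (phantom@state != "baseline")
    stop("pneumothorax induction requires a baseline phantom")
  specs <- if (is(spec, "PneumothoraxSpec")) list(spec) else spec
  stopifnot(all(vapply(specs, is, TRUE, "PneumothoraxSpec")))
  out <- phantom
  for (s in specs) out <- .applyPneumothorax(out, s)
  out@state <- "pneumothorax"
  validObject(out)
  out
}
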