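#' @name accessors
#' @title Accessors for dfpneumo data objects
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots.
#' @param object a dfpneumo S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("attenuationMap", function(object) standardGeneric("attenuationMap"))
#' @rdname accessors
#' @export
setGeneric("scatterMap", function(object) standardGeneric("scatterMap"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @param region region name from \code{labelTable(object)}.
#' @export
setGeneric("regionMask", function(object, region) standardGeneric("regionMask"))
#' @rdname accessors
#' @export
setGeneric("labelTable", function(object) standardGeneric("labelTable"))
#' @rdname accessors
#' @export
setGeneric("truthAreas", function(object) standardGeneric("truthAreas"))
#' @rdname accessors
#' @export
setGeneric("phantomState", function(object) standardGeneric("phantomState"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeCm", function(object) standardGeneric("pixelSizeCm"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("stepPhases", function(object) standardGeneric("stepPhases"))
#' @rdname accessors
#' @export
setGeneric("transmission", function(object) standardGeneric("transmission"))
#' @rdname accessors
#' @export
setGeneric("darkfield", function(object) standardGeneric("darkfield"))
#' @rdname accessors
#' @export
setGeneric("gapMask", function(object) standardGeneric("gapMask"))
#' @rdname accessors
#' @export
setGeneric("animalResults", function(object) standardGeneric("animalResults"))

#' @rdname accessors
#' @export
setMethod("attenuationMap", "ThoraxPhantom", function(object) object@attenuation)
#' @rdname accessors
#' @export
setMethod("scatterMap", "ThoraxPhantom", function(object) object@scatter)
#' @rdname accessors
#' @export
setMethod("regionLabels", "ThoraxPhantom", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("labelTable", "ThoraxPhantom", function(object) object@labelTable)
#' @rdname accessors
#' @export
setMethod("regionMask", "ThoraxPhantom", function(object, region) {
  if (!region %in% names(object@labelTable))
    stop("unknown region: ", region)
  object@labels == object@labelTable[[region]]
})
#' @rdname accessors
#' @export
setMethod("truthAreas", "ThoraxPhantom", function(object) object@truthAreasCm2)
#' @rdname accessors
#' @export
setMethod("phantomState", "ThoraxPhantom", function(object) object@state)
#' @rdname accessors
#' @export
setMethod("pixelSizeCm", "ThoraxPhantom", function(object) object@pixelSizeCm)
#' @rdname accessors
#' @export
setMethod("frames", "SteppingScan", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("stepPhases", "SteppingScan", function(object) object@phases)
#' @rdname accessors
#' @export
setMethod("transmission", "RadiographPair", function(object) object@transmission)
#' @rdname accessors
#' @export
setMethod("darkfield", "RadiographPair", function(object) object@darkfield)
#' @rdname accessors
#' @export
setMethod("gapMask", "RadiographPair", function(object) object@gapMask)
#' @rdname accessors
#' @export
setMethod("animalResults", "CohortResult", function(object) object@animals)

setMethod("show", "ScannerGeometry", function(object) {
  cat("ScannerGeometry (fringe-scanning prototype)\n")
  cat(sprintf("  gratings: G0 %.2f um (duty %.1f) | G1 %.2f um | G2 %.0f um\n",
              object@p0Um, object@duty0, object@p1Um, object@p2Um))
  cat(sprintf("  distances: source-detector %.2g m, G0-G1 %.2f m, G1-G2 %.2f m\n",
              object@sourceDetectorM, object@dG0G1M, object@dG1G2M))
  cat(sprintf("  pixels: true %.0f um, effective %.0f um; FOV %g x %g cm\n",
              object@truePixelUm, object@effectivePixelUm,
              object@fovObjectCm[1], object@fovObjectCm[2]))
  cat(sprintf("  reference visibility v0 = %.3g\n", object@v0))
})

setMethod("show", "ThoraxPhantom", function(object) {
  d <- dim(object@attenuation)
  cat(sprintf("ThoraxPhantom [%s]: %d x %d px at %.3f cm/px\n",
              object@state, d[1], d[2], object@pixelSizeCm))
  ta <- object@truthAreasCm2
  cat(sprintf("  retro-diaphragmatic lung truth: left %.1f cm2, right %.1f cm2\n",
              ta[["retro_diaphragmatic_lung_left"]],
              ta[["retro_diaphragmatic_lung_right"]]))
  cat(sprintf("  regions present: %s\n",
              paste(names(object@labelTable)[object@labelTable %in%
                                               unique(c(object@labels))],
                    collapse = ", ")))
})

setMethod("show", "SteppingScan", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SteppingScan: %d x %d px, %d phase steps%s\n",
              d[1], d[2], d[3],
              if (isTRUE(object@meta$noiseless)) " (noiseless)" else ""))
})

setMethod("show", "RadiographPair", function(object) {
  d <- dim(object@transmission)
  cat(sprintf("RadiographPair: %d x %d px (registered T/D)\n", d[1], d[2]))
  cat(sprintf("  T in [%.3f, %.3f], D in [%.3f, %.3f], %d gap px\n",
              min(object@transmission), max(object@transmission),
              min(object@darkfield), max(object@darkfield),
              sum(object@gapMask)))
})

setMethod("show", "CohortResult", function(object) {
  a <- object@animals
  cat(sprintf("CohortResult: %d animals (%d lateral, %d dorsal-only; %d in vivo)\n",
              nrow(a), sum(a$type == "lateral"), sum(a$type == "dorsal"),
              sum(a$group == "in_vivo")))
  if (length(object@summary)) {
    s <- object@summary
    cat(sprintf("  CNR (lateral): DF filt %.2f+-%.2f, DF %.2f+-%.2f, T %.2f+-%.2f, T filt %.2f+-%.2f\n",
                s$cnr["df_filtered", "mean"], s$cnr["df_filtered", "sd"],
                s$cnr["df_unfiltered", "mean"], s$cnr["df_unfiltered", "sd"],
                s$cnr["t_unfiltered", "mean"], s$cnr["t_unfiltered", "sd"],
                s$cnr["t_filtered", "mean"], s$cnr["t_filtered", "sd"]))
    cat(sprintf("  retro area change: affected %.1f%% (p = %.2g), control %.1f%% (p = %.2g)\n",
                s$area$affected$pctChange, s$area$affected$p,
                s$area$control$pctChange, s$area$control$p))
  }
})
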