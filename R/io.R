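## 32-bit float TIFF writer. The tiff package stores [0, 1]; images are
## rescaled by their max and the scale recorded in a JSON sidecar so the
## reader restores physical values.
writeImageTiff <- function(img, path) {
  img[is.na(img)] <- 0
  mx <- max(img, 1e-12)
  tiff::writeTIFF(img / mx, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = mx, rows = nrow(img), cols = ncol(img)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

readImageTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  tiff::readTIFF(path) * meta$scale
}

#' Write a phantom to disk
#'
#' Attenuation and scatter maps as 32-bit float TIFF (one file per map,
#' with a JSON scale sidecar each), region masks as 8-bit labeled TIFF plus
#' a JSON label dictionary, truth areas as CSV.
#'
#' @param phantom a \linkS4class{ThoraxPhantom}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the written file paths.
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(dir, sprintf("%s_%s", prefix, x))
  writeImageTiff(phantom@attenuation, p("attenuation.tif"))
  writeImageTiff(phantom@scatter, p("scatter.tif"))
  tiff::writeTIFF(phantom@labels / 255, p("labels.tif"), bits.per.sample = 8L)
  jsonlite::write_json(as.list(phantom@labelTable), p("labels.json"),
                       auto_unbox = TRUE)
  utils::write.csv(
    data.frame(region = names(phantom@truthAreasCm2),
               area_cm2 = unname(phantom@truthAreasCm2),
               state = phantom@state,
               pixel_size_cm = phantom@pixelSizeCm),
    p("truth.csv"), row.names = FALSE)
  invisible(c(p("attenuation.tif"), p("scatter.tif"), p("labels.tif"),
              p("labels.json"), p("truth.csv")))
}

#' Write a retrieved radiograph pair to disk
#'
#' Transmission and dark-field as 32-bit float TIFF, gap mask as 8-bit
#' TIFF, provenance as YAML.
#'
#' @param pair a \linkS4class{RadiographPair}.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Invisibly, the written file paths.
#' @export
writeRadiographPair <- function(pair, dir, prefix = "radiograph") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(dir, sprintf("%s_%s", prefix, x))
  writeImageTiff(pair@transmission, p("transmission.tif"))
  writeImageTiff(pair@darkfield, p("darkfield.tif"))
  tiff::writeTIFF((pair@gapMask * 1), p("gapmask.tif"), bits.per.sample = 8L)
  yaml::write_yaml(pair@provenance[!vapply(pair@provenance, is.null, TRUE)],
                   p("provenance.yaml"))
  invisible(c(p("transmission.tif"), p("darkfield.tif"), p("gapmask.tif"),
              p("provenance.yaml")))
}

#' Persist a stepping scan as a multi-page TIFF with a YAML sidecar
#'
#' @param scan a \linkS4class{SteppingScan}.
#' @param path output TIFF path; the sidecar is written next to it.
#' @return Invisibly, \code{path}.
#' @export
writeSteppingScan <- function(scan, path) {
  mx <- max(scan@frames, 1e-12)
  pages <- lapply(seq_len(dim(scan@frames)[3]),
                  function(k) scan@frames[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(scale = mx, phases = as.numeric(scan@phases),
                        nSteps = length(scan@phases),
                        seed = scan@meta$settings@rngSeed,
                        noiseless = isTRUE(scan@meta$noiseless)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a stepping scan written by \code{\link{writeSteppingScan}}
#'
#' @param path TIFF path with its YAML sidecar.
#' @return A \linkS4class{SteppingScan} (provenance limited to the sidecar).
#' @export
readSteppingScan <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  fr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) fr[, , k] <- pages[[k]] * meta$scale
  new("SteppingScan", frames = fr, phases = as.numeric(meta$phases),
      meta = list(noiseless = isTRUE(meta$noiseless), sidecar = meta))
}
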