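rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.animalSeed <- function(cohortSeed, i, salt = 0) {
  as.integer((as.double(cohortSeed) * 131 + i * 7919 + salt) %% 2147483629)
}

#' Generate a synthetic cohort of phantom pairs
#'
#' Draws per-animal parameters from the cohort distributions of the
#' calibration (anterior-posterior diameter, lung scale and scatter level,
#' baseline retro-diaphragmatic areas, instilled air volume, dorsal
#' collapse fraction) and builds one (baseline, pneumothorax) phantom pair
#' per animal. By default the cohort mirrors the study layout: 8 animals,
#' the first 3 ex vivo and the rest in vivo, 6 with a lateral pneumothorax
#' and 2 (in vivo) with a dorsal-only pneumothorax. Every animal receives
#' the dorsal collapse of its affected side -- pleural air accumulates
#' dorsally in the prone animal regardless of where the pleural line is
#' visible -- and lateral animals additionally receive the lateral gas
#' band.
#'
#' @param nAnimals number of animals (>= 1).
#' @param cohortSeed integer seed; the whole cohort is reproducible.
#' @param calibration preset name or override list, see \code{\link{calibrationPreset}}.
#' @param scale phantom grid scale (see \code{\link{phantomConfig}}).
#' @param nLateral number of animals with a lateral pneumothorax; default
#'   \code{nAnimals - 2} when the cohort has at least 8 animals, otherwise
#'   all of them.
#' @param phantoms build the phantom pairs (default); \code{FALSE} returns
#'   the drawn parameters only.
#' @return List with \code{animals} (list of per-animal lists: metadata,
#'   \code{baseline} and \code{pneumo} phantoms) and \code{meta}
#'   (a data.frame of the drawn parameters).
#' @export
generateCohort <- function(nAnimals = 8L, cohortSeed = 1L,
                           calibration = "paper2018",
                           scale = "half", nLateral = NULL,
                           phantoms = TRUE) {
  stopifnot(nAnimals >= 1)
  calib <- calibrationPreset(calibration)
  cc <- calib$cohort
  if (is.null(nLateral))
    nLateral <- if (nAnimals >= 8) nAnimals - 2L else nAnimals
  stopifnot(nLateral <= nAnimals)
  nExVivo <- min(3L, nLateral)
  draws <- withSeed(cohortSeed, {
    data.frame(
      animal = seq_len(nAnimals),
      group = ifelse(seq_len(nAnimals) <= nExVivo, "ex_vivo", "in_vivo"),
      type = ifelse(seq_len(nAnimals) <= nLateral, "lateral", "dorsal"),
      side = sample(c("left", "right"), nAnimals, replace = TRUE),
      apDiameterCm = rtruncnorm1(nAnimals, cc$apDiameterMeanCm,
                                 cc$apDiameterSdCm, 14, 28),
      lungScale = rtruncnorm1(nAnimals, 1, cc$lungScaleSd, 0.9, 1.1),
      scatterLung = rtruncnorm1(nAnimals, calib$phantom$scatterLung,
                                cc$scatterLungSd, 0.2, 0.6),
      affectedAreaCm2 = rtruncnorm1(nAnimals, cc$affectedAreaMeanCm2,
                                    cc$affectedAreaSdCm2, 40, 90),
      controlAreaCm2 = rtruncnorm1(nAnimals, cc$controlAreaMeanCm2,
                                   cc$controlAreaSdCm2, 30, 90),
      airVolumeMl = round(stats::runif(nAnimals,
                                       cc$lateralVolumeRangeMl[1],
                                       cc$lateralVolumeRangeMl[2])),
      collapseFraction = rtruncnorm1(nAnimals, cc$collapseMean,
                                     cc$collapseSd, 0.05, 0.4))
  })
  dorsalVol <- withSeed(cohortSeed + 1L, round(stats::runif(
    nAnimals, cc$dorsalVolumeRangeMl[1], cc$dorsalVolumeRangeMl[2])))
  draws$airVolumeMl[draws$type == "dorsal"] <- dorsalVol[draws$type == "dorsal"]
  if (!phantoms)
    return(list(animals = NULL, meta = draws, calibration = calibration,
                scale = scale, cohortSeed = cohortSeed))
  animals <- vector("list", nAnimals)
  for (i in seq_len(nAnimals)) {
    d <- draws[i, ]
    retro <- c(left = NA_real_, right = NA_real_)
    retro[d$side] <- d$affectedAreaCm2
    retro[setdiff(c("left", "right"), d$side)] <- d$controlAreaCm2
    cfg <- phantomConfig(
      scale = scale, apDiameterCm = d$apDiameterCm,
      retroAreaCm2 = retro, lungScale = d$lungScale,
      scatterLung = d$scatterLung,
      scatterRetro = calib$phantom$scatterRetro,
      muBody = calib$phantom$muBody, muLung = calib$phantom$muLung,
      muHeart = calib$phantom$muHeart, muRib = calib$phantom$muRib,
      muAbdomen = calib$phantom$muAbdomen,
      textureLungSd = calib$phantom$textureLungSd,
      textureLungFwhmPx = calib$phantom$textureLungFwhmPx,
      textureTransSd = calib$phantom$textureTransSd,
      textureTransFwhmPx = calib$phantom$textureTransFwhmPx,
      rngSeed = .animalSeed(cohortSeed, i))
    baseline <- generatePhantom(cfg)
    specs <- list(pneumothoraxSpec(d$side, "dorsal",
                                   collapseFraction = d$collapseFraction))
    if (d$type == "lateral")
      specs <- c(specs, list(pneumothoraxSpec(d$side, "lateral",
                                              airVolumeMl = d$airVolumeMl)))
    pneumo <- inducePneumothorax(baseline, specs)
    animals[[i]] <- list(animal = i, group = d$group, type = d$type,
                         side = d$side, airVolumeMl = d$airVolumeMl,
                         collapseFraction = d$collapseFraction,
                         baseline = baseline, pneumo = pneumo)
  }
  list(animals = animals, meta = draws,
       calibration = calibration, scale = scale, cohortSeed = cohortSeed)
}
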