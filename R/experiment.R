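heartEdgeMask <- function(phantom) {
  h <- (phantom@labels == phantom@labelTable[["heart"]]) * 1
  b <- EBImage::makeBrush(5, "disc")
  (EBImage::dilate(h, b) - EBImage::erode(h, b)) > 0
}

## Full measurement chain for one animal: simulate both states, retrieve,
## filter, place ROIs, compute CNRs (lateral animals) and retro areas.
analyzeAnimal <- function(animal, geometry, settings, calib,
                          reference = NULL) {
  baseline <- animal$baseline
  pneumo <- animal$pneumo
  if (is.null(reference))
    reference <- simulateReference(geometry, settings,
                                   gridShape = dim(baseline@attenuation))
  scanB <- simulateScan(baseline, geometry, settings)
  scanP <- simulateScan(pneumo, geometry, settings)
  if (identical(animal$group, "in_vivo") && calib$motionAmplitude > 0) {
    edge <- heartEdgeMask(baseline)
    scanB <- addMotionArtifact(scanB, edge, calib$motionAmplitude)
    scanP <- addMotionArtifact(scanP, edge, calib$motionAmplitude)
  }
  pairB <- retrieveRadiographs(scanB, reference)
  pairP <- retrieveRadiographs(scanP, reference)
  dfPF <- gaussianLowpass(darkfield(pairP), calib$filterFwhmPx)
  trPF <- gaussianLowpass(transmission(pairP), calib$filterFwhmPx)
  res <- data.frame(animal = animal$animal, group = animal$group,
                    type = animal$type, side = animal$side,
                    airVolumeMl = animal$airVolumeMl,
                    collapseFraction = animal$collapseFraction,
                    cnrDfFiltered = NA_real_, cnrDfUnfiltered = NA_real_,
                    cnrTUnfiltered = NA_real_, cnrTFiltered = NA_real_)
  if (animal$type == "lateral") {
    rois <- autoPlaceROIs(pneumo, roiSideCm = calib$roiSideCm)
    res$cnrDfFiltered <- cnr(dfPF, rois$lung, rois$pneumo)
    res$cnrDfUnfiltered <- cnr(darkfield(pairP), rois$lung, rois$pneumo)
    res$cnrTUnfiltered <- cnr(transmission(pairP), rois$lung, rois$pneumo)
    res$cnrTFiltered <- cnr(trPF, rois$lung, rois$pneumo)
  }
  px <- baseline@pixelSizeCm
  ctlSide <- setdiff(c("left", "right"), animal$side)
  for (role in c("affected", "control")) {
    side <- if (role == "affected") animal$side else ctlSide
    band <- retroAnalysisBand(baseline, side)
    mB <- segmentInflatedLung(darkfield(pairB), band,
                              calib$segThresholdFactor, calib$filterFwhmPx)
    mP <- segmentInflatedLung(darkfield(pairP), band,
                              calib$segThresholdFactor, calib$filterFwhmPx)
    lab <- sprintf("retro_diaphragmatic_lung_%s", side)
    res[[sprintf("area%sBefore", capFirst(role))]] <-
      projectedArea(mB, px)
    res[[sprintf("area%sAfter", capFirst(role))]] <-
      projectedArea(mP, px)
    res[[sprintf("truth%sBefore", capFirst(role))]] <-
      truthAreas(baseline)[[lab]]
    res[[sprintf("truth%sAfter", capFirst(role))]] <-
      truthAreas(pneumo)[[lab]]
  }
  res
}

#' Analyze a generated cohort end to end
#'
#' Simulates the fringe-scanning acquisition of every animal in both
#' states (with the cardiac motion artifact for in-vivo animals), retrieves
#' transmission/dark-field pairs against a shared noiseless reference,
#' applies the quantitative Gaussian filter, places ROIs, computes the four
#' lung-to-pneumothorax CNRs per lateral animal and the retro-diaphragmatic
#' projected areas (affected and control side, both states), and summarizes
#' the cohort.
#'
#' @param cohort output of \code{\link{generateCohort}}.
#' @return A \linkS4class{CohortResult}.
#' @export
analyzeCohort <- function(cohort) {
  calib <- calibrationPreset(cohort$calibration)
  geometry <- scannerGeometry(v0 = calib$v0)
  gridShape <- dim(cohort$animals[[1]]$baseline@attenuation)
  refSettings <- acquisitionSettings(nSteps = calib$nSteps,
                                     photonsPerStep = calib$photonsPerStep,
                                     poissonNoise = calib$noisyReference,
                                     rngSeed = cohort$cohortSeed)
  reference <- simulateReference(geometry, refSettings, gridShape = gridShape)
  rows <- lapply(cohort$animals, function(a) {
    settings <- acquisitionSettings(
      nSteps = calib$nSteps, photonsPerStep = calib$photonsPerStep,
      rngSeed = .animalSeed(cohort$cohortSeed, a$animal, salt = 17))
    analyzeAnimal(a, geometry, settings, calib, reference = reference)
  })
  animals <- do.call(rbind, rows)
  summary <- if (nrow(animals) >= 2) cohortSummary(animals) else list()
  new("CohortResult", animals = animals, summary = summary)
}

#' Cohort summary statistics
#'
#' Means and standard deviations of the four CNRs over the lateral animals,
#' affected/control retro-diaphragmatic areas before and after induction
#' with the mean per-animal percent change and paired two-tailed t-tests,
#' and the unpaired two-tailed comparison of ex-vivo vs in-vivo CNRs.
#' Percent change is the mean of per-animal percent changes (not the
#' percent change of the means).
#'
#' @param animals per-animal data.frame (\code{animalResults} of a
#'   \linkS4class{CohortResult}) or a \linkS4class{CohortResult}.
#' @return List with elements \code{cnr} (matrix), \code{area} (affected /
#'   control comparisons) and \code{exVivoInVivo} (p-values per modality).
#' @export
cohortSummary <- function(animals) {
  if (is(animals, "CohortResult")) animals <- animals@animals
  if (nrow(animals) < 2)
    stop("cohort statistics require at least 2 animals per comparison")
  need <- c("areaAffectedBefore", "areaAffectedAfter",
            "areaControlBefore", "areaControlAfter")
  missing <- need[vapply(need, function(n) anyNA(animals[[n]]), TRUE)]
  if (length(missing))
    stop("missing measurements for: ", paste(missing, collapse = ", "))
  lat <- animals[animals$type == "lateral", ]
  cols <- c(df_filtered = "cnrDfFiltered", df_unfiltered = "cnrDfUnfiltered",
            t_unfiltered = "cnrTUnfiltered", t_filtered = "cnrTFiltered")
  cnrMat <- t(vapply(cols, function(cl)
    c(mean = mean(lat[[cl]]), sd = stats::sd(lat[[cl]])), numeric(2)))
  area <- list()
  for (role in c("affected", "control")) {
    b <- animals[[sprintf("area%sBefore", capFirst(role))]]
    a <- animals[[sprintf("area%sAfter", capFirst(role))]]
    tt <- pairedTTest(b, a)
    area[[role]] <- list(
      meanBefore = mean(b), sdBefore = stats::sd(b),
      meanAfter = mean(a), sdAfter = stats::sd(a),
      pctChange = mean(100 * (a - b) / b), p = tt$p, t = tt$t, n = length(b))
  }
  exInVivo <- list(transmission = NA_real_, darkfield = NA_real_)
  ex <- lat[lat$group == "ex_vivo", ]
  iv <- lat[lat$group == "in_vivo", ]
  if (nrow(ex) >= 2 && nrow(iv) >= 2) {
    exInVivo$transmission <- stats::t.test(ex$cnrTUnfiltered,
                                           iv$cnrTUnfiltered,
                                           var.equal = TRUE)$p.value
    exInVivo$darkfield <- stats::t.test(ex$cnrDfFiltered, iv$cnrDfFiltered,
                                        var.equal = TRUE)$p.value
  }
  list(cnr = cnrMat, area = area, exVivoInVivo = exInVivo,
       nAnimals = nrow(animals), nLateral = nrow(lat))
}

#' Run repeated cohort experiments
#'
#' Generates and analyzes \code{nCohorts} independent cohorts with seeds
#' derived from \code{baseSeed}, returning the pooled per-animal table and
#' the per-cohort summaries. This is the in-memory workhorse behind
#' \code{\link{runExperiment}} and the acceptance checks.
#'
#' @param nCohorts number of cohorts.
#' @param baseSeed integer; cohort j uses seed \code{baseSeed * 1000 + j - 1}.
#' @param nAnimals,nLateral,scale,calibration passed to
#'   \code{\link{generateCohort}}.
#' @return List with \code{animals} (data.frame, one row per animal with a
#'   \code{cohort} column) and \code{summaries} (list of cohort summaries).
#' @export
runCohortAnalysis <- function(nCohorts, baseSeed = 1L, nAnimals = 8L,
                              nLateral = NULL, scale = "half",
                              calibration = "paper2018") {
  seeds <- (as.double(baseSeed) * 1000 + seq_len(nCohorts) - 1) %% 2147483629
  out <- vector("list", nCohorts)
  for (j in seq_len(nCohorts)) {
    cohort <- generateCohort(nAnimals, as.integer(seeds[j]), calibration,
                             scale, nLateral)
    res <- analyzeCohort(cohort)
    a <- res@animals
    a$cohort <- j
    out[[j]] <- list(animals = a, summary = res@summary)
  }
  list(animals = do.call(rbind, lapply(out, `[[`, "animals")),
       summaries = lapply(out, `[[`, "summary"))
}

#' Run the full experiment with file outputs
#'
#' Orchestrates the complete pipeline for one cohort: phantom generation,
#' stepping-scan simulation (reference plus baseline and pneumothorax
#' states, motion artifact for in-vivo animals), retrieval, filtering, ROI
#' placement, CNR and projected-area quantification and cohort statistics.
#' Writes retrieved image pairs (TIFF), the per-animal results CSV, a
#' human-readable summary and a manifest recording configuration and every
#' seed. Bit-identical outputs for a fixed configuration.
#'
#' @param config named list or path to a YAML file with any of:
#'   \code{outDir} (required), \code{seed}, \code{nAnimals}, \code{nLateral},
#'   \code{scale}, \code{calibration}, \code{writeImages}.
#' @return Invisibly, the \linkS4class{CohortResult}.
#' @export
runExperiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outDir))
  cfg <- utils::modifyList(
    list(seed = 1L, nAnimals = 8L, nLateral = NULL, scale = "half",
         calibration = "paper2018", writeImages = TRUE), config)
  cfg$seed <- as.integer(cfg$seed)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(stage, t0)
    message(sprintf("[%s] %s (%.1f s)", format(Sys.time(), "%H:%M:%S"),
                    stage, as.numeric(Sys.time()) - t0))
  tStart <- as.numeric(Sys.time())
  cohort <- generateCohort(cfg$nAnimals, as.integer(cfg$seed),
                           cfg$calibration, cfg$scale, cfg$nLateral)
  stamp("phantom cohort generated", tStart)
  tAnalysis <- as.numeric(Sys.time())
  res <- analyzeCohort(cohort)
  stamp("simulation + retrieval + analysis", tAnalysis)
  if (isTRUE(cfg$writeImages)) {
    tWrite <- as.numeric(Sys.time())
    calib <- calibrationPreset(cfg$calibration)
    geometry <- scannerGeometry(v0 = calib$v0)
    refSettings <- acquisitionSettings(calib$nSteps, calib$photonsPerStep,
                                       calib$noisyReference,
                                       cohort$cohortSeed)
    reference <- simulateReference(
      geometry, refSettings,
      gridShape = dim(cohort$animals[[1]]$baseline@attenuation))
    for (a in cohort$animals) {
      settings <- acquisitionSettings(
        calib$nSteps, calib$photonsPerStep,
        rngSeed = .animalSeed(cohort$cohortSeed, a$animal, salt = 17))
      for (state in c("baseline", "pneumo")) {
        scan <- simulateScan(a[[state]], geometry, settings)
        if (identical(a$group, "in_vivo") && calib$motionAmplitude > 0)
          scan <- addMotionArtifact(scan, heartEdgeMask(a$baseline),
                                    calib$motionAmplitude)
        pair <- retrieveRadiographs(scan, reference)
        writeRadiographPair(pair, file.path(cfg$outDir, "images"),
                            prefix = sprintf("animal%02d_%s", a$animal, state))
      }
      writePhantom(a$baseline, file.path(cfg$outDir, "phantoms"),
                   prefix = sprintf("animal%02d_baseline", a$animal))
    }
    stamp("images written", tWrite)
  }
  utils::write.csv(res@animals, file.path(cfg$outDir, "results.csv"),
                   row.names = FALSE)
  s <- res@summary
  rpt <- c(
    "Cohort experiment summary",
    sprintf("animals: %d (%d lateral)", s$nAnimals, s$nLateral),
    "",
    "Lung-to-pneumothorax CNR (lateral animals, mean +- sd):",
    sprintf("  dark-field, filtered   : %.2f +- %.2f",
            s$cnr["df_filtered", "mean"], s$cnr["df_filtered", "sd"]),
    sprintf("  dark-field, unfiltered : %.2f +- %.2f",
            s$cnr["df_unfiltered", "mean"], s$cnr["df_unfiltered", "sd"]),
    sprintf("  transmission, unfiltered: %.2f +- %.2f",
            s$cnr["t_unfiltered", "mean"], s$cnr["t_unfiltered", "sd"]),
    sprintf("  transmission, filtered : %.2f +- %.2f",
            s$cnr["t_filtered", "mean"], s$cnr["t_filtered", "sd"]),
    "",
    "Retro-diaphragmatic projected lung area (cm2):",
    sprintf("  affected side: %.1f +- %.1f -> %.1f +- %.1f (%+.1f%%, p = %.4f)",
            s$area$affected$meanBefore, s$area$affected$sdBefore,
            s$area$affected$meanAfter, s$area$affected$sdAfter,
            s$area$affected$pctChange, s$area$affected$p),
    sprintf("  control side : %.1f +- %.1f -> %.1f +- %.1f (%+.1f%%, p = %.4f)",
            s$area$control$meanBefore, s$area$control$sdBefore,
            s$area$control$meanAfter, s$area$control$sdAfter,
            s$area$control$pctChange, s$area$control$p),
    "",
    sprintf("ex vivo vs in vivo CNR: p(Transmission) = %.2f, p(Dark-field) = %.2f",
            s$exVivoInVivo$transmission, s$exVivoInVivo$darkfield))
  writeLines(rpt, file.path(cfg$outDir, "summary.txt"))
  yaml::write_yaml(list(
    config = cfg[!vapply(cfg, is.null, TRUE)],
    cohortSeed = cohort$cohortSeed,
    animalPhantomSeeds = vapply(seq_len(cfg$nAnimals), function(i)
      .animalSeed(cohort$cohortSeed, i), numeric(1)),
    animalPhotonSeeds = vapply(seq_len(cfg$nAnimals), function(i)
      .animalSeed(cohort$cohortSeed, i, salt = 17), numeric(1))),
    file.path(cfg$outDir, "manifest.yaml"))
  invisible(res)
}
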