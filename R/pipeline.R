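## End-to-end pipeline driver. Ties the stages together on a synthetic world
## (or pre-generated inputs written by the io helpers): generate covariates
## and records, thin, build the accessible area, fit and evaluate the
## candidate niche-model grid, build the median consensus and the binary
## potential-distribution map, fit and select occupancy models, fuse the two
## scales into the realized distribution, and compute EOO/AOO comparators.
## Every stage is an exported function; this driver is glue plus artifact
## writing, so the whole analysis is reproducible from a config and seeds.

#' Pipeline configuration
#'
#' Assembles every tunable of the synthetic end-to-end run, with defaults
#' emulating the stated study design: ~1-km covariate cells, a correlated
#' layer pair (r = 0.92) split across two variable sets, 1-km occurrence
#' thinning, a 50-km buffered accessible area, a regularization grid from
#' 0.1 to 5 with l/q/lq features, a 20 percent test split, 30 sites x 5
#' occasions with 5 unconducted surveys, detection-first model selection,
#' and a third-quartile integration threshold.
#'
#' @param seed master integer seed; stage seeds are derived from it
#' @param nRows,nCols,cellSize,autocorrRange,nLayers landscape settings
#'   (see [landscapeSpec()])
#' @param nOccurrences records drawn before thinning
#' @param biasStrength sampling-bias strength
#' @param lambdaTrue generating Gibbs weights (one per layer)
#' @param regValues,featureLabels candidate-grid axes
#' @param backgroundMax background sample cap
#' @param nBoot partial-ROC bootstrap iterations
#' @param nSites,nOccasions,missingFraction detection design
#' @param betaPsiTrue,alphaPTrue generating occupancy/detection coefficients
#'   (intercepts first; psi covariates Veg_H and Hori0, p covariates N_obj
#'   and Soil_moisture)
#' @param gofSims parametric-bootstrap simulations for the GOF test
#' @param fineFactor fine grid refinement factor for the integration stage
#' @param integrationQuantile threshold quantile of the masked occupancy map
#' @param aooCellKm AOO grid size in km
#' @return a list of class "PipelineConfig"
#' @export
pipelineConfig <- function(seed = 1L, nRows = 90, nCols = 90,
                           cellSize = 0.01, autocorrRange = 7, nLayers = 6,
                           nOccurrences = 250, biasStrength = 0.5,
                           lambdaTrue = c(0, 1.5, -1, 0.8, 0.5, 0),
                           regValues = c(0.1, 0.5, 1, 2, 5),
                           featureLabels = c("l", "q", "lq"),
                           backgroundMax = 5000, nBoot = 200,
                           nSites = 30, nOccasions = 5,
                           missingFraction = 5 / 150,
                           betaPsiTrue = c(qlogis(0.45), -1.2, 0),
                           alphaPTrue = c(qlogis(0.35), 0.9, 0),
                           gofSims = 200, fineFactor = 8,
                           integrationQuantile = 0.75, aooCellKm = 2) {
  structure(as.list(environment()), class = "PipelineConfig")
}

## Stage seed derived from the master seed; kept inside 32-bit range.
stageSeed <- function(seed, k) as.integer((as.numeric(seed) * 131 + k) %%
                                          2147483647)

#' Run the full two-scale range-estimation pipeline on a synthetic world
#'
#' Executes every stage in order and (optionally) writes the artifacts:
#' covariate rasters and the suitability/consensus/binary grids as ASCII
#' rasters, occurrence and model tables as CSV, polygons as GeoJSON, and a
#' JSON run summary with seeds, thresholds, selected model ids and areas.
#'
#' @param config a [pipelineConfig()]
#' @param outDir output directory, or NULL to skip writing
#' @return (invisibly) a list with every intermediate object and a
#'   \code{summary} element mirroring the JSON run metadata
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  ## -- synthetic world ------------------------------------------------------
  spec <- landscapeSpec(cfg$nRows, cfg$nCols, cfg$cellSize,
                        autocorrRange = cfg$autocorrRange,
                        nLayers = cfg$nLayers, seed = stageSeed(cfg$seed, 1))
  stack <- generateEnvStack(spec)
  truth <- truthParams(lambdaTrue = cfg$lambdaTrue,
                       betaPsiTrue = cfg$betaPsiTrue,
                       alphaPTrue = cfg$alphaPTrue,
                       missingFraction = cfg$missingFraction)
  occRaw <- sampleOccurrences(stack, truth, cfg$nOccurrences,
                              cfg$biasStrength, seed = stageSeed(cfg$seed, 2))
  ## -- occurrence prep ------------------------------------------------------
  occ <- thinOccurrences(occRaw, minDistKm = 1)
  ext <- c(stack@origin[1], stack@origin[2] - cfg$nRows * cfg$cellSize,
           stack@origin[1] + cfg$nCols * cfg$cellSize, stack@origin[2])
  regions <- calibrationArea(rbind(
    c(ext[1], ext[2]), c(ext[3], ext[2]), c(ext[3], ext[4]),
    c(ext[1], ext[4])))
  accessible <- buildAccessibleArea(occ, bufferKm = 50, regions = regions)
  masked <- maskToArea(stack, accessible)
  ## two variable sets: the correlated pair (layers 1 and 2, ground-level vs
  ## atmospheric temperature stand-ins) is split across the sets, everything
  ## else shared; each set is auto-filtered to |rho| < 0.8 internally
  nms <- layerNames(stack)
  shared <- nms[-(1:2)]
  setDefs <- list(set_1 = c(nms[1], shared), set_2 = c(nms[2], shared))
  sets <- buildVariableSets(masked, setDefs, threshold = 0.8,
                            autoFilter = TRUE)
  ## -- candidate niche models ----------------------------------------------
  split <- makeDataSplit(nRecords(occ), 0.2, seed = stageSeed(cfg$seed, 3))
  candidates <- runCandidateGrid(occ, sets, cfg$regValues,
                                 cfg$featureLabels, split,
                                 backgroundMax = cfg$backgroundMax,
                                 seed = stageSeed(cfg$seed, 4))
  metrics <- evaluateCandidates(candidates, sets, E = 5, nBoot = cfg$nBoot,
                                seed = stageSeed(cfg$seed, 5))
  selected <- selectModels(metrics)
  if (!length(selected)) {
    warning("no candidate met all criteria; falling back to the ",
            "minimum-AICc candidate")
    selected <- metrics$modelId[which.min(metrics$aicc)]
  }
  ## -- consensus, threshold, potential distribution ------------------------
  selGrids <- lapply(selected, function(id)
    predictGrid(candidates[[id]]$model, sets[[candidates[[id]]$set]]))
  consensus <- consensusMedian(selGrids)
  thresholds <- vapply(selected, function(id) {
    cand <- candidates[[id]]
    stackS <- sets[[cand$set]]
    spec <- structure(list(classes = cand$model@featureClasses,
                           bounds = cand$model@scalingBounds),
                      class = "FeatureSpec")
    trainSuit <- predictCloglog(cand$model,
                                makeFeatures(stackS, spec, cand$trainCells))
    trainingPresenceThreshold(trainSuit, E = 10)
  }, 0)
  threshold <- mean(thresholds)
  potential <- binarize(consensus, threshold, stack@origin, stack@cellSize,
                        provenance = selected)
  potentialArea <- areaKm2(potential)
  ## -- occupancy ------------------------------------------------------------
  ## natural-unit habitat rasters: vegetation height (m) driven by layer 3,
  ## 0-horizon depth (cm) by layer 5; sites are valid cells inside M
  vegH <- pmax(2.8 + 1.3 * stack@layers[[3]], 0.1)
  hori0 <- pmax(6 + 2 * stack@layers[[5]], 0.5)
  set.seed(stageSeed(cfg$seed, 6))
  siteCells <- sample(validCells(masked), cfg$nSites)
  siteCov <- data.frame(Veg_H = vegH[siteCells], Hori0 = hori0[siteCells])
  nObj <- matrix(rep(rpois(cfg$nSites, 4), cfg$nOccasions),
                 cfg$nSites, cfg$nOccasions)
  soil <- matrix(runif(cfg$nSites * cfg$nOccasions, 10, 60),
                 cfg$nSites, cfg$nOccasions)
  surveyCov <- list(N_obj = nObj, Soil_moisture = soil)
  det <- simulateDetectionHistories(siteCov, surveyCov, truth,
                                    cfg$nSites, cfg$nOccasions,
                                    seed = stageSeed(cfg$seed, 7))
  detectionCandidates <- list(character(0), "N_obj", "Soil_moisture",
                              c("N_obj", "Soil_moisture"))
  occupancyCandidates <- list(character(0), "Veg_H", "Hori0",
                              c("Veg_H", "Hori0"))
  selection <- twoStageSelection(det, detectionCandidates,
                                 occupancyCandidates,
                                 seed = stageSeed(cfg$seed, 8))
  bestFit <- selection$bestFit
  gof <- parametricBootstrapGOF(bestFit, det, nSim = cfg$gofSims,
                                seed = stageSeed(cfg$seed, 9))
  ## -- integration ----------------------------------------------------------
  fineCell <- cfg$cellSize / cfg$fineFactor
  fineDim <- c(cfg$nRows, cfg$nCols) * cfg$fineFactor
  natural <- envStack(list(Veg_H = vegH, Hori0 = hori0), stack@origin,
                      cfg$cellSize, nodataMask = masked@nodataMask)
  fine <- resampleToGrid(natural, stack@origin, fineCell, fineDim)
  realized <- integrateModels(potential, bestFit, fine,
                              probs = cfg$integrationQuantile)
  ## -- range metrics --------------------------------------------------------
  ranges <- rangeSummary(occ, cfg$aooCellKm)
  summary <- list(
    seed = cfg$seed,
    n_occurrences_raw = nRecords(occRaw),
    n_occurrences_thinned = nRecords(occ),
    accessible_area_km2 = polygonAreaKm2(accessible),
    n_candidates = length(candidates),
    selected_models = as.list(selected),
    suitability_threshold = threshold,
    potential_area_km2 = potentialArea,
    naive_occupancy = naiveOccupancy(det),
    best_detection_covariates = as.list(selection$bestDetection),
    best_occupancy_model = modelLabel(bestFit),
    best_occupancy_aicc = bestFit@aicc,
    gof_statistic = gof$statistic,
    gof_pval = gof$pval,
    occupancy_threshold = realized@threshold,
    realized_area_km2 = realized@areaKm2,
    realized_over_potential = realized@areaKm2 / potentialArea,
    eoo_km2 = ranges@eooKm2,
    aoo_km2 = ranges@aooKm2)
  result <- list(config = cfg, stack = stack, occurrences = occ,
                 accessibleArea = accessible, sets = sets,
                 candidates = candidates, metrics = metrics,
                 selected = selected, consensus = consensus,
                 potential = potential, detectionData = det,
                 selection = selection, bestFit = bestFit, gof = gof,
                 fineStack = fine, realized = realized, ranges = ranges,
                 summary = summary)
  if (!is.null(outDir)) writePipelineArtifacts(result, outDir)
  invisible(result)
}

## Write the pipeline artifacts: rasters, tables, polygons, JSON summary.
writePipelineArtifacts <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeEnvStack(result$stack, file.path(outDir, "env"))
  writeOccurrences(result$occurrences, file.path(outDir, "occurrences.csv"))
  writeAreaGeoJSON(result$accessibleArea,
                   file.path(outDir, "accessible_area.geojson"))
  s <- result$stack
  writeAsciiGrid(result$consensus, s@origin, s@cellSize,
                 file.path(outDir, "consensus_suitability.asc"))
  writeAsciiGrid(result$potential@grid, s@origin, s@cellSize,
                 file.path(outDir, "potential_binary.asc"))
  writeAsciiGrid(result$realized@grid, result$fineStack@origin,
                 result$fineStack@cellSize,
                 file.path(outDir, "realized_binary.asc"))
  write.csv(result$metrics, file.path(outDir, "candidate_metrics.csv"),
            row.names = FALSE)
  writeModelTable(result$selection$stage1Table,
                  file.path(outDir, "detection_model_table.csv"))
  writeModelTable(result$selection$stage2Table,
                  file.path(outDir, "occupancy_model_table.csv"))
  writeDetectionData(result$detectionData, file.path(outDir, "detection"))
  jsonlite::write_json(result$summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
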