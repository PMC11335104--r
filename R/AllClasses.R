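#' @import methods
#' @importFrom stats quantile cor optim optimHess rnorm runif rbinom rpois
#'   sd plogis qlogis qnorm median setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices chull
NULL

## Central S4 containers. Grids are plain matrices (row 1 = northernmost row)
## with a geographic transform: `origin` is the (lon, lat) of the upper-left
## corner of the upper-left cell and `cellSize` the square cell size in
## decimal degrees (WGS84, cell-center registration). All cell <-> coordinate
## arithmetic lives in geometry.R and uses this convention.

#' OccurrenceSet: georeferenced point records of a species
#'
#' Wraps a data frame of presence records (id, lon, lat, source). Sources are
#' one of "collection", "community", "field", "synthetic".
#'
#' @slot records data.frame with columns id, lon, lat, source
#' @export
setClass("OccurrenceSet", representation(records = "data.frame"))

setValidity("OccurrenceSet", function(object) {
  r <- object@records
  msg <- character(0)
  need <- c("id", "lon", "lat", "source")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$id)) msg <- c(msg, "record ids must be unique")
    if (any(r$lon < -180 | r$lon > 180, na.rm = TRUE))
      msg <- c(msg, "lon must lie in [-180, 180]")
    if (any(r$lat < -90 | r$lat > 90, na.rm = TRUE))
      msg <- c(msg, "lat must lie in [-90, 90]")
    ok <- c("collection", "community", "field", "synthetic")
    if (!all(r$source %in% ok))
      msg <- c(msg, paste("source must be one of", paste(ok, collapse = "/")))
  }
  if (length(msg)) msg else TRUE
})

#' CalibrationArea: a (multi-part) polygon in geographic coordinates
#'
#' Each part is an n x 2 matrix of (lon, lat) vertices of a simple ring;
#' rings are stored unclosed (first vertex not repeated).
#'
#' @slot parts list of numeric matrices, each n x 2
#' @export
setClass("CalibrationArea", representation(parts = "list"))

setValidity("CalibrationArea", function(object) {
  if (!length(object@parts)) return("polygon must be non-empty")
  for (p in object@parts) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      return("each part must be an n x 2 matrix with n >= 3")
    if (any(!is.finite(p))) return("polygon vertices must be finite")
  }
  TRUE
})

#' EnvStack: an aligned multi-layer environmental raster grid
#'
#' @slot layers named list of numeric matrices sharing one shape
#' @slot origin numeric(2), (lon, lat) of the upper-left grid corner
#' @slot cellSize numeric(1), cell size in decimal degrees
#' @slot nodataMask logical matrix, TRUE where a cell is nodata in all layers
#' @slot setId character(1) variable-set label
#' @export
setClass("EnvStack", representation(
  layers = "list", origin = "numeric", cellSize = "numeric",
  nodataMask = "matrix", setId = "character"))

setValidity("EnvStack", function(object) {
  if (!length(object@layers)) return("at least one layer required")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    return("layers must be uniquely named")
  d <- dim(object@layers[[1]])
  for (l in object@layers)
    if (!is.matrix(l) || !identical(dim(l), d))
      return("all layers must be matrices of the same shape")
  if (!is.logical(object@nodataMask) || !identical(dim(object@nodataMask), d))
    return("nodataMask must be a logical matrix matching the layers")
  if (length(object@origin) != 2) return("origin must be (lon, lat)")
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    return("cellSize must be a positive scalar")
  for (l in object@layers)
    if (any(!is.na(l[object@nodataMask])))
      return("masked cells must be NA in every layer")
  TRUE
})

#' MaxentModel: a fitted maximum-entropy niche model
#'
#' Stores the L1-penalized feature weights (lambda), the normalization over
#' the background sample, and the entropy of the fitted Gibbs distribution
#' used by the cloglog transform.
#'
#' @slot lambda named numeric feature weights
#' @slot regMultiplier positive scalar scaling the default L1 penalties
#' @slot featureClasses one of "l", "q", "lq"
#' @slot scalingBounds 2 x nLayers matrix (min/max per layer over background)
#' @slot backgroundIds integer cell indices of the background sample
#' @slot logZ log normalization constant over the background
#' @slot entropyH entropy of the raw distribution over the background
#' @slot setId variable-set label
#' @slot converged logical
#' @export
setClass("MaxentModel", representation(
  lambda = "numeric", regMultiplier = "numeric", featureClasses = "character",
  scalingBounds = "matrix", backgroundIds = "integer", logZ = "numeric",
  entropyH = "numeric", setId = "character", converged = "logical"))

setValidity("MaxentModel", function(object) {
  if (object@regMultiplier <= 0) return("regMultiplier must be positive")
  if (!object@featureClasses %in% c("l", "q", "lq"))
    return("featureClasses must be one of l/q/lq")
  TRUE
})

#' DetectionData: sites x occasions detection histories with covariates
#'
#' @slot y integer matrix over {0, 1, NA}; NA marks an unconducted survey
#' @slot siteCovariates data.frame, one row per site (standardized)
#' @slot surveyCovariates named list of site x occasion matrices (standardized)
#' @slot standardization data.frame(covariate, mean, sd) recording the
#'   transformation applied, so natural units can be recovered
#' @export
setClass("DetectionData", representation(
  y = "matrix", siteCovariates = "data.frame", surveyCovariates = "list",
  standardization = "data.frame"))

setValidity("DetectionData", function(object) {
  y <- object@y
  if (!all(y[!is.na(y)] %in% c(0L, 1L)))
    return("non-missing detections must be 0 or 1")
  if (any(rowSums(!is.na(y)) < 1))
    return("every site needs at least one conducted survey")
  if (nrow(object@siteCovariates) &&
      nrow(object@siteCovariates) != nrow(y))
    return("siteCovariates rows must match the number of sites")
  for (m in object@surveyCovariates)
    if (!identical(dim(m), dim(y)))
      return("each surveyCovariates matrix must match dim(y)")
  TRUE
})

#' OccupancyFit: a fitted single-season occupancy model
#'
#' @slot betaPsi occupancy coefficients on the logit scale, intercept first
#' @slot alphaP detection coefficients on the logit scale, intercept first
#' @slot psiCovariates,pCovariates covariate names entering each linear
#'   predictor (may be empty: intercept-only)
#' @slot logLik maximized log-likelihood
#' @slot K total coefficient count
#' @slot aicc small-sample-corrected AIC with n = number of sites
#' @slot nSites number of sites
#' @slot vcov observed-information covariance of all coefficients
#' @slot standardization covariate standardization record inherited from the data
#' @slot converged logical
#' @export
setClass("OccupancyFit", representation(
  betaPsi = "numeric", alphaP = "numeric",
  psiCovariates = "character", pCovariates = "character",
  logLik = "numeric", K = "numeric", aicc = "numeric", nSites = "numeric",
  vcov = "matrix", standardization = "data.frame", converged = "logical"))

setValidity("OccupancyFit", function(object) {
  if (object@K != length(object@betaPsi) + length(object@alphaP))
    return("K must equal the total coefficient count")
  TRUE
})

#' BinaryMap: a thresholded presence/absence grid
#'
#' @slot grid matrix over {0, 1, NA}
#' @slot origin,cellSize geographic transform (see EnvStack)
#' @slot threshold suitability threshold applied
#' @slot provenance model ids the map derives from
#' @export
setClass("BinaryMap", representation(
  grid = "matrix", origin = "numeric", cellSize = "numeric",
  threshold = "numeric", provenance = "character"))

#' RealizedDistribution: the fused fine-resolution binary range map
#'
#' @slot grid fine-resolution matrix over {0, 1, NA}
#' @slot origin,cellSize geographic transform
#' @slot threshold occupancy threshold used (third quartile by default)
#' @slot sourceModels ids of the niche and occupancy models fused
#' @slot areaKm2 total area of 1-cells in square kilometres
#' @export
setClass("RealizedDistribution", representation(
  grid = "matrix", origin = "numeric", cellSize = "numeric",
  threshold = "numeric", sourceModels = "character", areaKm2 = "numeric"))

#' RangeSummary: IUCN-style extent-of-occurrence / area-of-occupancy summary
#'
#' @slot eooKm2 convex-hull (extent of occurrence) area, km^2
#' @slot aooKm2 occupied-grid-cell (area of occupancy) area, km^2
#' @slot aooCellKm AOO grid cell edge, km (IUCN default 2)
#' @slot nPoints number of occurrence points used
#' @export
setClass("RangeSummary", representation(
  eooKm2 = "numeric", aooKm2 = "numeric", aooCellKm = "numeric",
  nPoints = "numeric"))

## show methods -------------------------------------------------------------

setMethod("show", "OccurrenceSet", function(object) {
  r <- object@records
  cat("OccurrenceSet with", nrow(r), "records\n")
  if (nrow(r)) {
    cat("  lon: [", round(min(r$lon), 4), ",", round(max(r$lon), 4), "]\n")
    cat("  lat: [", round(min(r$lat), 4), ",", round(max(r$lat), 4), "]\n")
    cat("  sources:", paste(names(table(r$source)), table(r$source),
                            sep = ":", collapse = " "), "\n")
  }
})

setMethod("show", "EnvStack", function(object) {
  d <- dim(object@layers[[1]])
  cat("EnvStack '", object@setId, "': ", length(object@layers), " layers, ",
      d[1], " x ", d[2], " cells @ ", object@cellSize, " deg\n", sep = "")
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
  cat("  nodata cells:", sum(object@nodataMask), "\n")
})

setMethod("show", "MaxentModel", function(object) {
  cat("MaxentModel (", object@featureClasses, " features, reg ",
      object@regMultiplier, ", set ", object@setId, ")\n", sep = "")
  cat("  nonzero weights:", sum(object@lambda != 0), "of",
      length(object@lambda), "\n")
  cat("  entropy:", round(object@entropyH, 4), "\n")
})

setMethod("show", "DetectionData", function(object) {
  y <- object@y
  cat("DetectionData:", nrow(y), "sites x", ncol(y), "occasions;",
      sum(!is.na(y)), "conducted surveys,", sum(y == 1, na.rm = TRUE),
      "detections\n")
  cat("  site covariates:", paste(names(object@siteCovariates),
                                  collapse = ", "), "\n")
  if (length(object@surveyCovariates))
    cat("  survey covariates:", paste(names(object@surveyCovariates),
                                      collapse = ", "), "\n")
})

setMethod("show", "OccupancyFit", function(object) {
  cat("OccupancyFit ", modelLabel(object), "\n", sep = "")
  cat("  logLik ", round(object@logLik, 3), ", K ", object@K, ", AICc ",
      round(object@aicc, 3), if (!object@converged) "  [NOT CONVERGED]",
      "\n", sep = "")
})

setMethod("show", "BinaryMap", function(object) {
  cat("BinaryMap:", sum(object@grid == 1, na.rm = TRUE), "presence cells @",
      object@cellSize, "deg, threshold", round(object@threshold, 4), "\n")
})

setMethod("show", "RealizedDistribution", function(object) {
  cat("RealizedDistribution:", sum(object@grid == 1, na.rm = TRUE),
      "cells @", object@cellSize, "deg; area",
      round(object@areaKm2, 1), "km^2; threshold",
      round(object@threshold, 3), "\n")
})

setMethod("show", "RangeSummary", function(object) {
  cat("RangeSummary: EOO", round(object@eooKm2, 1), "km^2; AOO",
      round(object@aooKm2, 1), "km^2 (", object@aooCellKm, "km grid,",
      object@nPoints, "points )\n")
})
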