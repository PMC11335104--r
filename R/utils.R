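## Shared numerics and constructors.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Akaike deltas, weights, and cumulative weights from AICc values
#'
#' The Akaike machinery shared by the niche-model candidate table and the
#' occupancy model tables: delta = AICc - min(AICc), weight proportional to
#' exp(-delta/2), cumulative weight accumulated in ascending-AICc order.
#'
#' @param aicc numeric vector of AICc values
#' @param labels optional model labels
#' @return data.frame(label, aicc, deltaAicc, aiccWeight, cumulativeWeight),
#'   sorted ascending by AICc (ties kept in label order)
#' @export
akaikeTable <- function(aicc, labels = NULL) {
  stopifnot(length(aicc) >= 1, all(is.finite(aicc)))
  if (is.null(labels)) labels <- paste0("model_", seq_along(aicc))
  o <- order(aicc, labels)
  aicc <- aicc[o]; labels <- labels[o]
  delta <- aicc - aicc[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  data.frame(label = labels, aicc = aicc, deltaAicc = delta,
             aiccWeight = w, cumulativeWeight = cumsum(w),
             stringsAsFactors = FALSE)
}

## AICc from a log-likelihood, parameter count and sample size.
aiccValue <- function(logLik, K, n) {
  if (n <= K + 1) return(NA_real_)
  2 * K - 2 * logLik + 2 * K * (K + 1) / (n - K - 1)
}

#' Construct an OccurrenceSet
#'
#' @param lon,lat coordinates in decimal degrees (WGS84)
#' @param id record identifiers (defaults to occ_0001, ...)
#' @param source provenance tag, recycled; one of collection/community/field/
#'   synthetic
#' @return an [OccurrenceSet-class] object
#' @export
occurrenceSet <- function(lon, lat, id = NULL,
                          source = "synthetic") {
  n <- length(lon)
  stopifnot(length(lat) == n)
  if (is.null(id)) id <- sprintf("occ_%04d", seq_len(n))
  new("OccurrenceSet", records = data.frame(
    id = as.character(id), lon = as.numeric(lon), lat = as.numeric(lat),
    source = rep_len(as.character(source), n), stringsAsFactors = FALSE))
}

#' Records of an OccurrenceSet as a data frame
#' @param x an OccurrenceSet
#' @return data.frame with columns id, lon, lat, source
#' @export
occurrenceRecords <- function(x) x@records

#' Number of records in an OccurrenceSet
#' @param x an OccurrenceSet
#' @export
nRecords <- function(x) nrow(x@records)

#' Construct an EnvStack from matrices
#'
#' @param layers named list of numeric matrices (row 1 = northernmost row)
#' @param origin (lon, lat) of the upper-left grid corner, decimal degrees
#' @param cellSize cell size in decimal degrees
#' @param nodataMask optional logical matrix; defaults to cells NA in any layer
#' @param setId variable-set label
#' @return an [EnvStack-class]
#' @export
envStack <- function(layers, origin, cellSize, nodataMask = NULL,
                     setId = "set_1") {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(nodataMask)) {
    nodataMask <- Reduce(`|`, lapply(layers, is.na))
  }
  layers <- lapply(layers, function(l) { l[nodataMask] <- NA_real_; l })
  new("EnvStack", layers = layers, origin = as.numeric(origin),
      cellSize = as.numeric(cellSize), nodataMask = nodataMask,
      setId = setId)
}

#' Layer names of an EnvStack
#' @param x an EnvStack
#' @export
layerNames <- function(x) names(x@layers)

#' Extract one layer matrix from an EnvStack
#' @param x an EnvStack
#' @param name layer name
#' @export
envLayer <- function(x, name) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  x@layers[[name]]
}

#' Linear indices of usable (non-nodata) cells of an EnvStack
#' @param x an EnvStack
#' @export
validCells <- function(x) which(!x@nodataMask)

#' Longitude/latitude of cell centers for given linear cell indices
#' @param x an EnvStack
#' @param idx linear cell indices (default: all valid cells)
#' @return matrix with columns lon, lat
#' @export
cellCenters <- function(x, idx = validCells(x)) {
  d <- dim(x@layers[[1]])
  cellCenterCoords(idx, d[1], d[2], x@origin, x@cellSize)
}

## Subset an EnvStack to named layers (shared mask kept).
subsetLayers <- function(x, names) {
  missing <- setdiff(names, layerNames(x))
  if (length(missing))
    stop("missing layer name(s): ", paste(missing, collapse = ", "))
  envStack(x@layers[names], x@origin, x@cellSize, x@nodataMask, x@setId)
}

## Human-readable "p(...) psi(...)" label for an occupancy fit.
modelLabel <- function(fit) {
  pLab <- if (length(fit@pCovariates))
    paste(fit@pCovariates, collapse = "+") else "."
  psiLab <- if (length(fit@psiCovariates))
    paste(fit@psiCovariates, collapse = "+") else "."
  sprintf("p(%s) psi(%s)", pLab, psiLab)
}
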