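## Integration of the two scales: project the best occupancy model onto a
## fine-resolution covariate grid, keep only cells whose containing coarse
## niche-map cell is suitable, binarize at the third quartile of the masked
## occupancy values, and account areas in km^2.

#' Project an occupancy model onto a fine-resolution covariate stack
#'
#' Cellwise inverse-logit of the fitted linear predictor. Layers are given
#' in natural units and standardized internally using the record stored on
#' the fit; nodata propagates.
#'
#' @param fit an [OccupancyFit-class]
#' @param fineCovariates an [EnvStack-class] containing a layer for every
#'   psi covariate of the fit
#' @return a numeric matrix of occupancy probabilities
#' @export
projectOccupancy <- function(fit, fineCovariates) {
  missing <- setdiff(fit@psiCovariates, layerNames(fineCovariates))
  if (length(missing))
    stop("fine stack lacks psi covariate layer(s): ",
         paste(missing, collapse = ", "))
  d <- dim(fineCovariates@layers[[1]])
  eta <- matrix(fit@betaPsi["(Intercept)"], d[1], d[2])
  std <- fit@standardization
  for (nm in fit@psiCovariates) {
    l <- envLayer(fineCovariates, nm)
    i <- match(nm, std$covariate)
    if (!is.na(i)) l <- (l - std$mean[i]) / std$sd[i]
    eta <- eta + fit@betaPsi[nm] * l
  }
  out <- plogis(eta)
  out[fineCovariates@nodataMask] <- NA_real_
  out
}

#' Mask a fine grid to the suitable cells of a coarse binary map
#'
#' A fine cell is retained iff the coarse cell containing its center equals
#' 1; all other fine cells become nodata. The two grids need only share the
#' georeference, not an alignment.
#'
#' @param coarse a [BinaryMap-class]
#' @param fineGrid numeric matrix of fine-resolution values
#' @param fineOrigin,fineCellSize geographic transform of the fine grid
#' @return the masked fine matrix
#' @export
maskAndRefine <- function(coarse, fineGrid, fineOrigin, fineCellSize) {
  nrF <- nrow(fineGrid); ncF <- ncol(fineGrid)
  nrC <- nrow(coarse@grid); ncC <- ncol(coarse@grid)
  idx <- seq_len(nrF * ncF)
  xy <- cellCenterCoords(idx, nrF, ncF, fineOrigin, fineCellSize)
  cIdx <- cellIndexOf(xy[, "lon"], xy[, "lat"], nrC, ncC, coarse@origin,
                      coarse@cellSize)
  if (all(is.na(cIdx))) stop("coarse and fine extents are disjoint")
  keep <- !is.na(cIdx) & !is.na(coarse@grid[ifelse(is.na(cIdx), 1, cIdx)]) &
          coarse@grid[ifelse(is.na(cIdx), 1, cIdx)] == 1
  out <- fineGrid
  out[idx[!keep]] <- NA_real_
  out
}

#' Binarize a masked occupancy grid at its third quartile
#'
#' The threshold is the \code{probs} quantile of the non-nodata values,
#' interpolated linearly between order statistics under the convention that
#' assigns the k-th order statistic probability k/(n+1) (quantile type 6, so
#' the third quartile of \{0.1, 0.2, 0.3, 0.4\} is 0.375); cells with psi >=
#' threshold become 1. A constant grid yields a degenerate threshold with a
#' warning (all cells tie at 1).
#'
#' @param maskedPsi numeric matrix of masked occupancy probabilities
#' @param origin,cellSize geographic transform of the grid
#' @param probs quantile defining the threshold (default 0.75)
#' @param sourceModels model ids this map derives from
#' @return a [RealizedDistribution-class]
#' @export
q3Binarize <- function(maskedPsi, origin = c(0, 0), cellSize = 1,
                       probs = 0.75, sourceModels = character(0)) {
  vals <- maskedPsi[!is.na(maskedPsi)]
  if (length(vals) < 4)
    stop("need at least 4 non-nodata cells to take a quartile")
  if (diff(range(vals)) == 0)
    warning("constant occupancy grid: degenerate threshold, all cells tie")
  thr <- unname(quantile(vals, probs, type = 6))
  grid <- ifelse(is.na(maskedPsi), NA_real_,
                 as.numeric(maskedPsi >= thr))
  new("RealizedDistribution", grid = grid, origin = as.numeric(origin),
      cellSize = cellSize, threshold = thr, sourceModels = sourceModels,
      areaKm2 = gridCellAreaKm2(grid, origin, cellSize))
}

#' Area of the presence cells of a binary grid, in km^2
#'
#' Latitude-dependent spherical-degree approximation: each 1-cell
#' contributes (cellSize x 111.320 x cos(lat)) x (cellSize x 110.574) km^2.
#'
#' @param x a [BinaryMap-class], [RealizedDistribution-class], or a plain
#'   binary matrix (then origin/cellSize are required)
#' @param origin,cellSize geographic transform for a plain matrix
#' @return area in km^2
#' @export
areaKm2 <- function(x, origin = NULL, cellSize = NULL) {
  if (is(x, "BinaryMap") || is(x, "RealizedDistribution"))
    return(gridCellAreaKm2(x@grid, x@origin, x@cellSize))
  stopifnot(is.matrix(x), !is.null(origin), !is.null(cellSize))
  gridCellAreaKm2(x, origin, cellSize)
}

#' Fuse a coarse binary niche map with an occupancy model
#'
#' Convenience wrapper: [projectOccupancy()] on the fine stack,
#' [maskAndRefine()] against the coarse map, [q3Binarize()] of the result.
#'
#' @param coarse a [BinaryMap-class] from the consensus niche model
#' @param fit the best [OccupancyFit-class]
#' @param fineCovariates fine-resolution [EnvStack-class] in natural units
#' @param probs threshold quantile (default third quartile)
#' @return a [RealizedDistribution-class]
#' @export
integrateModels <- function(coarse, fit, fineCovariates, probs = 0.75) {
  psi <- projectOccupancy(fit, fineCovariates)
  masked <- maskAndRefine(coarse, psi, fineCovariates@origin,
                          fineCovariates@cellSize)
  q3Binarize(masked, fineCovariates@origin, fineCovariates@cellSize, probs,
             sourceModels = c(coarse@provenance, modelLabel(fit)))
}
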