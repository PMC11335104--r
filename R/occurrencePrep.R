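## Occurrence and raster preparation: spatial thinning, the accessible area
## M (buffered convex hull intersected with a region polygon), bilinear
## resampling to the modelling grid, and the Spearman correlation filter that
## yields uncorrelated variable sets.

#' Construct a CalibrationArea from one or more rings
#'
#' @param ... one or more n x 2 matrices of (lon, lat) vertices, or a single
#'   list of them
#' @return a [CalibrationArea-class]
#' @export
calibrationArea <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.matrix(parts[[1]]))
    parts <- parts[[1]]
  parts <- lapply(parts, function(p) dedupeRing(as.matrix(p)))
  new("CalibrationArea", parts = parts)
}

#' Greedy spatial thinning of occurrence records
#'
#' Walks the records in input order and keeps a record iff its great-circle
#' distance (haversine, mean Earth radius 6371.0088 km) to every
#' already-kept record is at least \code{minDistKm}. The result is a subset
#' of the input with all pairwise distances >= minDistKm; greedy in-order
#' retention makes the operation deterministic and idempotent.
#'
#' @param occ an [OccurrenceSet-class]
#' @param minDistKm minimum pairwise distance in km (> 0)
#' @return a thinned [OccurrenceSet-class]
#' @export
thinOccurrences <- function(occ, minDistKm = 1) {
  stopifnot(minDistKm > 0)
  r <- occ@records
  n <- nrow(r)
  if (n == 0) return(occ)
  keep <- logical(n)
  keptLon <- numeric(0); keptLat <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(keptLon) ||
        all(haversineKm(r$lon[i], r$lat[i], keptLon, keptLat) >= minDistKm)) {
      keep[i] <- TRUE
      keptLon <- c(keptLon, r$lon[i]); keptLat <- c(keptLat, r$lat[i])
    }
  }
  new("OccurrenceSet", records = r[keep, , drop = FALSE])
}

#' Build the accessible area M around occurrence records
#'
#' M is the convex hull of geodesic-approximate buffers of radius
#' \code{bufferKm} around each record, intersected with a larger region
#' polygon (e.g. biogeographic provinces). Buffers are discretized circles
#' computed in an azimuthal-equidistant projection centred on each record
#' and reprojected, so the 50-km radius is metrically faithful.
#'
#' @param occ an [OccurrenceSet-class] with >= 3 non-collinear records
#' @param bufferKm buffer radius in km (> 0)
#' @param regions a [CalibrationArea-class] to intersect with, or NULL to
#'   return the buffered hull itself
#' @param nArc vertices per buffer circle
#' @return a [CalibrationArea-class]
#' @export
buildAccessibleArea <- function(occ, bufferKm = 50, regions = NULL,
                                nArc = 72) {
  r <- occ@records
  stopifnot(nrow(r) >= 3, bufferKm > 0)
  theta <- seq(0, 2 * pi, length.out = nArc + 1)[-1]
  circ <- cbind(bufferKm * cos(theta), bufferKm * sin(theta))
  pts <- do.call(rbind, lapply(seq_len(nrow(r)), function(i)
    inverseAzimEquidistant(circ[, 1], circ[, 2], r$lon[i], r$lat[i])))
  hull <- convexHullRing(pts)
  if (is.null(regions)) return(calibrationArea(hull))
  clipped <- Filter(Negate(is.null),
                    lapply(regions@parts, clipRingConvex, clip = hull))
  clipped <- Filter(function(p) nrow(p) >= 3, clipped)
  if (!length(clipped))
    stop("accessible-area hull (", nrow(hull), " vertices around ",
         nrow(r), " records) does not intersect the region polygon (",
         length(regions@parts), " part(s))")
  calibrationArea(clipped)
}

#' Planar area of a CalibrationArea in km^2
#'
#' Shoelace area of each ring after projection to a Lambert azimuthal
#' equal-area plane centred on the area's vertex centroid.
#'
#' @param area a [CalibrationArea-class]
#' @export
polygonAreaKm2 <- function(area) {
  all <- do.call(rbind, area@parts)
  c0 <- colMeans(all)
  sum(vapply(area@parts, function(ring) {
    xy <- projectAzimEqualArea(ring[, 1], ring[, 2], c0[1], c0[2])
    abs(shoelaceArea(xy))
  }, 0))
}

#' Resample an EnvStack onto a target grid
#'
#' Continuous layers are interpolated bilinearly between source cell
#' centers; layers named in \code{categorical} use nearest-neighbour.
#' Target cells falling outside the source extent become nodata; values in
#' the half-cell rim beyond the outermost centers are edge-clamped.
#'
#' @param raw source [EnvStack-class]
#' @param targetOrigin (lon, lat) of the target upper-left corner
#' @param targetCellSize target cell size in degrees
#' @param targetDim c(nRows, nCols) of the target grid
#' @param categorical character vector of layer names to resample
#'   nearest-neighbour
#' @return an [EnvStack-class] on the target grid
#' @export
resampleToGrid <- function(raw, targetOrigin, targetCellSize, targetDim,
                           categorical = character(0)) {
  nrS <- nrow(raw@layers[[1]]); ncS <- ncol(raw@layers[[1]])
  nrT <- targetDim[1]; ncT <- targetDim[2]
  ## fractional source cell coordinates of each target cell center
  lonT <- targetOrigin[1] + (seq_len(ncT) - 0.5) * targetCellSize
  latT <- targetOrigin[2] - (seq_len(nrT) - 0.5) * targetCellSize
  colF <- (lonT - raw@origin[1]) / raw@cellSize + 0.5   # 1-based center coords
  rowF <- (raw@origin[2] - latT) / raw@cellSize + 0.5
  if (max(colF) < 0.5 || min(colF) > ncS + 0.5 ||
      max(rowF) < 0.5 || min(rowF) > nrS + 0.5)
    stop("source and target extents are disjoint")
  inX <- colF >= 0.5 & colF <= ncS + 0.5
  inY <- rowF >= 0.5 & rowF <= nrS + 0.5
  cf <- pmin(pmax(colF, 1), ncS); rf <- pmin(pmax(rowF, 1), nrS)
  c0 <- floor(cf); c1 <- pmin(c0 + 1, ncS); wc <- cf - c0
  r0 <- floor(rf); r1 <- pmin(r0 + 1, nrS); wr <- rf - r0
  bilinear <- function(l) {
    out <- matrix(NA_real_, nrT, ncT)
    for (j in seq_len(ncT)) {
      if (!inX[j]) next
      a <- l[r0, c0[j]] * (1 - wr) + l[r1, c0[j]] * wr
      b <- l[r0, c1[j]] * (1 - wr) + l[r1, c1[j]] * wr
      v <- a * (1 - wc[j]) + b * wc[j]
      v[!inY] <- NA_real_
      out[, j] <- v
    }
    out
  }
  nearest <- function(l) {
    out <- matrix(NA_real_, nrT, ncT)
    rn <- round(rf); cn <- round(cf)
    for (j in seq_len(ncT)) {
      if (!inX[j]) next
      v <- l[rn, cn[j]]
      v[!inY] <- NA_real_
      out[, j] <- v
    }
    out
  }
  out <- lapply(names(raw@layers), function(nm) {
    if (nm %in% categorical) nearest(raw@layers[[nm]])
    else bilinear(raw@layers[[nm]])
  })
  names(out) <- names(raw@layers)
  envStack(out, targetOrigin, targetCellSize, setId = raw@setId)
}

#' Mask an EnvStack to a calibration area
#'
#' Cells whose centers fall outside the area become nodata in every layer.
#'
#' @param stack an [EnvStack-class]
#' @param area a [CalibrationArea-class]
#' @return the masked [EnvStack-class]
#' @export
maskToArea <- function(stack, area) {
  d <- dim(stack@layers[[1]])
  idx <- seq_len(d[1] * d[2])
  xy <- cellCenterCoords(idx, d[1], d[2], stack@origin, stack@cellSize)
  outside <- !pointsInArea(xy[, "lon"], xy[, "lat"], area)
  mask <- stack@nodataMask
  mask[idx[outside]] <- TRUE
  if (all(mask)) stop("no grid cell center falls inside the area")
  envStack(stack@layers, stack@origin, stack@cellSize, mask, stack@setId)
}

#' Spearman correlation filter over a calibration area
#'
#' Computes the pairwise Spearman correlation matrix of all layers over the
#' non-nodata cells inside \code{area} (or the whole valid grid when area is
#' NULL), then keeps layers greedily in input order: a layer is retained iff
#' |rho| < threshold against every already-retained layer.
#'
#' @param stack an [EnvStack-class] with >= 2 layers
#' @param area optional [CalibrationArea-class] restricting the cells used
#' @param threshold absolute-correlation cutoff in (0, 1]
#' @return list(stack = retained EnvStack, correlations = full Spearman
#'   matrix, dropped = dropped layer names)
#' @export
correlationFilter <- function(stack, area = NULL, threshold = 0.8) {
  stopifnot(length(stack@layers) >= 2, threshold > 0, threshold <= 1)
  use <- if (is.null(area)) stack else maskToArea(stack, area)
  idx <- validCells(use)
  if (!length(idx)) stop("the area contains no usable (non-nodata) cells")
  vals <- vapply(use@layers, function(l) l[idx], numeric(length(idx)))
  rho <- cor(vals, method = "spearman")
  nms <- layerNames(stack)
  kept <- character(0)
  for (nm in nms) {
    if (!length(kept) || all(abs(rho[nm, kept]) < threshold))
      kept <- c(kept, nm)
  }
  list(stack = subsetLayers(stack, kept), correlations = rho,
       dropped = setdiff(nms, kept))
}

#' Split a stack into named variable sets
#'
#' One EnvStack per set definition. With \code{autoFilter = TRUE} each set is
#' passed through [correlationFilter()] so it is internally uncorrelated;
#' otherwise a correlated pair inside a set is an error.
#'
#' @param stack an [EnvStack-class]
#' @param setDefinitions named list: set id -> character vector of layer names
#' @param area optional [CalibrationArea-class] for the correlation check
#' @param threshold absolute-correlation cutoff
#' @param autoFilter drop offending layers (TRUE) or fail (FALSE)
#' @return named list of [EnvStack-class] objects
#' @export
buildVariableSets <- function(stack, setDefinitions, area = NULL,
                              threshold = 0.8, autoFilter = FALSE) {
  stopifnot(length(setDefinitions) >= 1)
  out <- list()
  for (sid in names(setDefinitions)) {
    nms <- setDefinitions[[sid]]
    if (!length(nms)) stop("set '", sid, "' is empty")
    missing <- setdiff(nms, layerNames(stack))
    if (length(missing))
      stop("set '", sid, "' names missing layer(s): ",
           paste(missing, collapse = ", "))
    sub <- subsetLayers(stack, nms)
    sub@setId <- sid
    if (length(nms) >= 2) {
      cf <- correlationFilter(sub, area, threshold)
      if (length(cf$dropped)) {
        if (!autoFilter)
          stop("set '", sid, "' contains correlated layer(s): ",
               paste(cf$dropped, collapse = ", "))
        sub <- cf$stack
        sub@setId <- sid
      }
    }
    out[[sid]] <- sub
  }
  out
}
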