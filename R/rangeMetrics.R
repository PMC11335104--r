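## IUCN-style range comparators from occurrence points: extent of occurrence
## (EOO, convex-hull area) and area of occupancy (AOO, occupied cells of a
## fixed 2-km grid). Both are computed in a Lambert azimuthal equal-area
## plane centred on the point centroid; the AOO grid is anchored at the
## projected origin (not optimized), for determinism.

#' Extent of occurrence: convex-hull area of the records
#'
#' @param occ an [OccurrenceSet-class] with at least 3 non-collinear records
#' @return area in km^2 (0, with a warning, for < 3 points or collinear sets)
#' @export
eoo <- function(occ) {
  r <- occ@records
  if (nrow(r) < 3) {
    warning("fewer than 3 points: EOO undefined, returning 0")
    return(0)
  }
  xy <- projectAzimEqualArea(r$lon, r$lat, mean(r$lon), mean(r$lat))
  hullIdx <- chull(xy[, 1], xy[, 2])
  if (length(hullIdx) < 3) {
    warning("collinear points: EOO degenerate, returning 0")
    return(0)
  }
  abs(shoelaceArea(xy[hullIdx, , drop = FALSE]))
}

#' Area of occupancy on a fixed grid
#'
#' Counts the distinct cellKm x cellKm grid cells (anchored at the projected
#' origin) containing at least one record; AOO = count x cellKm^2. The IUCN
#' default grid is 2 x 2 km. The projection is centred, by default, on the
#' point centroid rounded to whole degrees, so the grid anchor does not
#' drift as records accrue (and AOO stays monotone under point addition);
#' pass \code{center} to fix it explicitly.
#'
#' @param occ an [OccurrenceSet-class] with >= 1 record
#' @param cellKm grid cell edge in km (default 2)
#' @param center optional (lon, lat) projection centre
#' @return area in km^2
#' @export
aoo <- function(occ, cellKm = 2, center = NULL) {
  r <- occ@records
  stopifnot(nrow(r) >= 1, cellKm > 0)
  if (is.null(center)) center <- round(c(mean(r$lon), mean(r$lat)))
  xy <- projectAzimEqualArea(r$lon, r$lat, center[1], center[2])
  cells <- unique(paste(floor(xy[, 1] / cellKm), floor(xy[, 2] / cellKm)))
  length(cells) * cellKm^2
}

#' EOO/AOO summary of an occurrence set
#'
#' @inheritParams aoo
#' @return a [RangeSummary-class]
#' @export
rangeSummary <- function(occ, cellKm = 2) {
  new("RangeSummary", eooKm2 = eoo(occ), aooKm2 = aoo(occ, cellKm),
      aooCellKm = cellKm, nPoints = nRecords(occ))
}
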