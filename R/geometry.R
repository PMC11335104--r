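## Internal geometry. No GEOS-backed package is available, so the handful of
## planar/spherical primitives the pipeline needs are implemented here:
## haversine distances, azimuthal projections, convex hulls, polygon clipping
## against a convex ring, ray-casting containment, and shoelace areas.

EARTH_RADIUS_KM <- 6371.0088   # mean Earth radius
KM_PER_DEG_LON_EQ <- 111.320   # spherical-degree approximations used for
KM_PER_DEG_LAT    <- 110.574   # per-cell area accounting

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Great-circle distance in km between (lon1,lat1) and (lon2,lat2); vectorized.
haversineKm <- function(lon1, lat1, lon2, lat2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dphi <- phi2 - phi1; dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

## Azimuthal equidistant projection centred at (lon0, lat0); returns km.
projectAzimEquidistant <- function(lon, lat, lon0, lat0) {
  phi <- deg2rad(lat); phi0 <- deg2rad(lat0); dlam <- deg2rad(lon - lon0)
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cosc <- pmin(1, pmax(-1, cosc))
  c <- acos(cosc)
  k <- ifelse(c < 1e-12, 1, c / sin(c))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(dlam)
  y <- EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) -
                              sin(phi0) * cos(phi) * cos(dlam))
  cbind(x = x, y = y)
}

inverseAzimEquidistant <- function(x, y, lon0, lat0) {
  phi0 <- deg2rad(lat0)
  rho <- sqrt(x^2 + y^2)
  c <- rho / EARTH_RADIUS_KM
  lat <- ifelse(rho < 1e-12, lat0,
    rad2deg(asin(cos(c) * sin(phi0) + y * sin(c) * cos(phi0) / rho)))
  lon <- ifelse(rho < 1e-12, lon0,
    lon0 + rad2deg(atan2(x * sin(c),
      rho * cos(phi0) * cos(c) - y * sin(phi0) * sin(c))))
  cbind(lon = lon, lat = lat)
}

## Lambert azimuthal equal-area centred at (lon0, lat0); returns km. Used for
## EOO/AOO where areas must be preserved.
projectAzimEqualArea <- function(lon, lat, lon0, lat0) {
  phi <- deg2rad(lat); phi0 <- deg2rad(lat0); dlam <- deg2rad(lon - lon0)
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  kk <- sqrt(2 / pmax(denom, 1e-12))
  x <- EARTH_RADIUS_KM * kk * cos(phi) * sin(dlam)
  y <- EARTH_RADIUS_KM * kk * (cos(phi0) * sin(phi) -
                               sin(phi0) * cos(phi) * cos(dlam))
  cbind(x = x, y = y)
}

## Signed shoelace area of an unclosed ring (n x 2 matrix).
shoelaceArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## Convex hull of points, returned counter-clockwise and unclosed.
convexHullRing <- function(pts) {
  i <- chull(pts[, 1], pts[, 2])  # chull returns clockwise order
  ring <- pts[rev(i), , drop = FALSE]
  if (shoelaceArea(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
  ring
}

## Ray-casting point-in-polygon for one ring; boundary counts as inside
## within a small tolerance. Vectorized over points.
pointsInRing <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

pointsInArea <- function(lon, lat, area) {
  inside <- logical(length(lon))
  for (ring in area@parts) inside <- inside | pointsInRing(lon, lat, ring)
  inside
}

## Sutherland-Hodgman: clip an arbitrary subject ring against a CONVEX clip
## ring (counter-clockwise). Returns an unclosed ring matrix or NULL.
clipRingConvex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (k in seq_len(n)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[k, ]; b <- clip[if (k == n) 1 else k + 1, ]
    ## inside = left of directed edge a->b for a CCW clip ring
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
                        (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    m <- nrow(inp)
    for (i in seq_len(m)) {
      cur <- inp[i, ]; prv <- inp[if (i == 1) m else i - 1, ]
      sc <- side(cur); sp <- side(prv)
      if (sc >= 0) {
        if (sp < 0) out <- rbind(out, segIntersect(prv, cur, a, b))
        out <- rbind(out, cur)
      } else if (sp >= 0) {
        out <- rbind(out, segIntersect(prv, cur, a, b))
      }
    }
    if (nrow(out) < 3) return(NULL)
  }
  dedupeRing(out)
}

segIntersect <- function(p1, p2, a, b) {
  d1 <- p2 - p1; d2 <- b - a
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((a[1] - p1[1]) * d2[2] - (a[2] - p1[2]) * d2[1]) / den
  p1 + t * d1
}

dedupeRing <- function(ring, tol = 1e-12) {
  keep <- rep(TRUE, nrow(ring))
  for (i in seq_len(nrow(ring))) {
    j <- if (i == 1) nrow(ring) else i - 1
    if (i > 1 && all(abs(ring[i, ] - ring[j, ]) < tol)) keep[i] <- FALSE
  }
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) >= 2 && all(abs(ring[1, ] - ring[nrow(ring), ]) < tol))
    ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

## Grid helpers (cell-center registration, row 1 north) -----------------------

## lon/lat of cell centers for linear indices `idx` into an nr x nc matrix.
cellCenterCoords <- function(idx, nr, nc, origin, cellSize) {
  row <- ((idx - 1) %% nr) + 1
  col <- ((idx - 1) %/% nr) + 1
  cbind(lon = origin[1] + (col - 0.5) * cellSize,
        lat = origin[2] - (row - 0.5) * cellSize)
}

## Linear index of the cell containing each point; NA if outside the grid.
cellIndexOf <- function(lon, lat, nr, nc, origin, cellSize) {
  col <- floor((lon - origin[1]) / cellSize) + 1
  row <- floor((origin[2] - lat) / cellSize) + 1
  bad <- col < 1 | col > nc | row < 1 | row > nr
  idx <- (col - 1) * nr + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

## Latitude of the center of each grid row.
rowCenterLat <- function(nr, origin, cellSize)
  origin[2] - (seq_len(nr) - 0.5) * cellSize

## Area in km^2 of the 1-cells of a binary {0,1,NA} matrix under the
## spherical-degree approximation (latitude-dependent cell width).
gridCellAreaKm2 <- function(grid, origin, cellSize) {
  nr <- nrow(grid)
  lat <- rowCenterLat(nr, origin, cellSize)
  perRow <- (cellSize * KM_PER_DEG_LON_EQ * cos(deg2rad(lat))) *
            (cellSize * KM_PER_DEG_LAT)
  ones <- rowSums(grid == 1, na.rm = TRUE)
  sum(ones * perRow)
}
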