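## Plain-text file interfaces: ESRI ASCII grids for rasters, CSV for tabular
## data (comma-separated, UTF-8, "." decimal, "NA" for unconducted surveys),
## GeoJSON for polygons, JSON for run metadata. ASCII-grid I/O is written
## here because no raster package is available in the target environment.

#' Write a grid to an ESRI ASCII raster file
#'
#' @param grid numeric matrix (row 1 = northernmost row)
#' @param origin (lon, lat) of the upper-left grid corner
#' @param cellSize cell size in degrees
#' @param path output path (conventionally .asc)
#' @param nodata value written for NA cells
#' @export
writeAsciiGrid <- function(grid, origin, cellSize, path, nodata = -9999) {
  nr <- nrow(grid); nc <- ncol(grid)
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           paste("xllcorner", format(origin[1], digits = 15)),
           paste("yllcorner", format(origin[2] - nr * cellSize, digits = 15)),
           paste("cellsize", format(cellSize, digits = 15)),
           paste("NODATA_value", nodata))
  g <- grid
  g[is.na(g)] <- nodata
  body <- apply(g, 1, function(row)
    paste(format(row, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
}

#' Read an ESRI ASCII raster file
#'
#' @param path input path
#' @return list(grid, origin, cellSize)
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- hdr$nrows; nc <- hdr$ncols
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:(i + nr - 1)]), "\\s+")))
  grid <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) grid[grid == hdr$nodata_value] <- NA_real_
  list(grid = grid,
       origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
       cellSize = hdr$cellsize)
}

#' Write an EnvStack as one ASCII grid per layer
#'
#' Files are named <dir>/<layer>.asc.
#'
#' @param stack an [EnvStack-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the file paths
#' @export
writeEnvStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(layerNames(stack), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    writeAsciiGrid(stack@layers[[nm]], stack@origin, stack@cellSize, p)
    p
  }, "")
  invisible(paths)
}

#' Read a directory of ASCII grids into an EnvStack
#'
#' @param dir directory containing .asc files (layer name = file stem)
#' @param setId variable-set label
#' @return an [EnvStack-class]
#' @export
readEnvStack <- function(dir, setId = "set_1") {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc file in ", dir)
  grids <- lapply(files, readAsciiGrid)
  layers <- lapply(grids, `[[`, "grid")
  names(layers) <- sub("\\.asc$", "", basename(files))
  envStack(layers, grids[[1]]$origin, grids[[1]]$cellSize, setId = setId)
}

#' Write occurrences as CSV (columns id, lon, lat, source)
#' @param occ an [OccurrenceSet-class]
#' @param path output path
#' @export
writeOccurrences <- function(occ, path) {
  write.csv(occ@records, path, row.names = FALSE)
}

#' Read occurrences from a CSV with columns id, lon, lat, source
#' @param path input path
#' @return an [OccurrenceSet-class]
#' @export
readOccurrences <- function(path) {
  r <- read.csv(path, stringsAsFactors = FALSE)
  occurrenceSet(r$lon, r$lat, id = r$id, source = r$source)
}

#' Write detection data as CSVs
#'
#' Writes the detection matrix (columns occasion_1..J, "NA" marks an
#' unconducted survey), the site-covariate table, one CSV per survey
#' covariate, and the standardization record.
#'
#' @param data a [DetectionData-class]
#' @param dir output directory
#' @export
writeDetectionData <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  y <- as.data.frame(data@y)
  names(y) <- paste0("occasion_", seq_len(ncol(data@y)))
  write.csv(cbind(site = seq_len(nrow(y)), y),
            file.path(dir, "detections.csv"), row.names = FALSE)
  write.csv(cbind(site = seq_len(nrow(y)), data@siteCovariates),
            file.path(dir, "site_covariates.csv"), row.names = FALSE)
  for (nm in names(data@surveyCovariates))
    write.csv(as.data.frame(data@surveyCovariates[[nm]]),
              file.path(dir, paste0("survey_", nm, ".csv")),
              row.names = FALSE)
  write.csv(data@standardization, file.path(dir, "standardization.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read detection data written by [writeDetectionData()]
#' @param dir input directory
#' @return a [DetectionData-class]
#' @export
readDetectionData <- function(dir) {
  det <- read.csv(file.path(dir, "detections.csv"))
  y <- as.matrix(det[, grep("^occasion_", names(det)), drop = FALSE])
  dimnames(y) <- NULL
  storage.mode(y) <- "integer"
  siteCov <- read.csv(file.path(dir, "site_covariates.csv"))
  siteCov$site <- NULL
  survFiles <- list.files(dir, pattern = "^survey_.*\\.csv$",
                          full.names = TRUE)
  surv <- lapply(survFiles, function(f) {
    m <- as.matrix(read.csv(f)); dimnames(m) <- NULL; m
  })
  names(surv) <- sub("^survey_(.*)\\.csv$", "\\1", basename(survFiles))
  stdPath <- file.path(dir, "standardization.csv")
  std <- if (file.exists(stdPath)) read.csv(stdPath, stringsAsFactors = FALSE)
         else data.frame(covariate = character(0), mean = numeric(0),
                         sd = numeric(0))
  new("DetectionData", y = y, siteCovariates = siteCov,
      surveyCovariates = surv, standardization = std)
}

#' Write a CalibrationArea as GeoJSON (MultiPolygon)
#' @param area a [CalibrationArea-class]
#' @param path output path
#' @export
writeAreaGeoJSON <- function(area, path) {
  coords <- lapply(area@parts, function(ring) {
    closed <- rbind(ring, ring[1, ])
    list(lapply(seq_len(nrow(closed)), function(i) closed[i, ]))
  })
  gj <- list(type = "MultiPolygon", coordinates = coords)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a GeoJSON Polygon/MultiPolygon into a CalibrationArea
#'
#' Accepts a bare geometry, a Feature, or a FeatureCollection (first
#' feature); only outer rings are kept.
#'
#' @param path input path
#' @return a [CalibrationArea-class]
#' @export
readAreaGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(gj$type) && gj$type == "FeatureCollection")
    gj <- gj$features[[1]]
  if (!is.null(gj$type) && gj$type == "Feature") gj <- gj$geometry
  ringToMatrix <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  parts <- switch(gj$type,
    Polygon = list(ringToMatrix(gj$coordinates[[1]])),
    MultiPolygon = lapply(gj$coordinates, function(poly)
      ringToMatrix(poly[[1]])),
    stop("unsupported GeoJSON geometry type: ", gj$type))
  calibrationArea(parts)
}

#' Write an occupancy model table in the conventional CSV layout
#'
#' Columns Model, K, AICc, Delta_AICc, AICcWt, Cum.Wt.
#'
#' @param table data.frame from [buildModelTable()]
#' @param path output path
#' @export
writeModelTable <- function(table, path) {
  out <- data.frame(Model = table$label, K = table$K, AICc = table$aicc,
                    Delta_AICc = table$deltaAicc, AICcWt = table$aiccWeight,
                    Cum.Wt = table$cumulativeWeight, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
}
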