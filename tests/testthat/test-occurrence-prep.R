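## km per degree of latitude used when constructing fixtures
latKm <- function(km) km / 111.19

test_that("thinning keeps forced subsets and respects all pairwise distances", {
  ## three collinear points at 0, 500, 1500 m: the middle one must go
  occ3 <- occurrenceSet(lon = c(0, 0, 0),
                        lat = c(0, latKm(0.5), latKm(1.5)))
  kept <- thinOccurrences(occ3, 1)
  expect_equal(occurrenceRecords(kept)$id,
               occurrenceRecords(occ3)$id[c(1, 3)])

  ## brute-force all-pairs oracle on a random set
  set.seed(42)
  occ <- occurrenceSet(lon = runif(120, -75.6, -75.3),
                       lat = runif(120, 6.5, 6.8))
  for (minD in c(1, 3, 8)) {
    th <- occurrenceRecords(thinOccurrences(occ, minD))
    if (nrow(th) > 1) {
      dmat <- outer(seq_len(nrow(th)), seq_len(nrow(th)), function(i, j)
        occuRange:::haversineKm(th$lon[i], th$lat[i], th$lon[j], th$lat[j]))
      expect_true(all(dmat[upper.tri(dmat)] >= minD))
    }
    expect_true(all(th$id %in% occurrenceRecords(occ)$id))
  }

  ## empty input is not an error
  expect_equal(nRecords(thinOccurrences(occurrenceSet(numeric(0),
                                                      numeric(0)), 1)), 0)
})

test_that("thinning is idempotent and monotone in the distance threshold", {
  set.seed(7)
  occ <- occurrenceSet(lon = runif(80, -75.6, -75.4),
                       lat = runif(80, 6.5, 6.7))
  once <- thinOccurrences(occ, 2)
  twice <- thinOccurrences(once, 2)
  expect_identical(occurrenceRecords(once), occurrenceRecords(twice))
  sizes <- vapply(c(0.5, 1, 2, 4, 8), function(d)
    nRecords(thinOccurrences(occ, d)), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("a 164-record set built around 54 separated anchors thins to 54", {
  ## 54 anchors >= 2 km apart; 110 satellites within ~150 m of an anchor,
  ## appended after the anchors so greedy in-order retention drops them all
  grid <- expand.grid(lon = seq(-75.6, by = 0.02, length.out = 9),
                      lat = seq(6.5, by = 0.02, length.out = 6))
  anchors <- grid[seq_len(54), ]
  set.seed(3)
  sat <- anchors[sample(54, 110, replace = TRUE), ]
  sat$lon <- sat$lon + runif(110, -1e-3, 1e-3)
  sat$lat <- sat$lat + runif(110, -1e-3, 1e-3)
  occ164 <- occurrenceSet(c(anchors$lon, sat$lon), c(anchors$lat, sat$lat),
                          source = "field")
  expect_equal(nRecords(occ164), 164)
  expect_equal(nRecords(thinOccurrences(occ164, 1)), 54)
})

test_that("the accessible area contains its generators and honours buffers", {
  set.seed(11)
  occ <- occurrenceSet(lon = runif(20, -75.5, -75.3),
                       lat = runif(20, 6.5, 6.7))
  bigRegion <- calibrationArea(rbind(c(-77, 5), c(-74, 5), c(-74, 8),
                                     c(-77, 8)))
  m <- buildAccessibleArea(occ, bufferKm = 50, regions = bigRegion)
  ## the hull of 50-km buffers contains at least one full disc
  expect_gte(polygonAreaKm2(m), pi * 50^2 * 0.99)
  ## every occurrence lies inside M (point-in-polygon oracle)
  r <- occurrenceRecords(occ)
  expect_true(all(occuRange:::pointsInArea(r$lon, r$lat, m)))

  ## idempotence: intersecting the hull with itself changes nothing
  hull <- buildAccessibleArea(occ, 50, regions = NULL)
  again <- buildAccessibleArea(occ, 50, regions = hull)
  expect_equal(polygonAreaKm2(again), polygonAreaKm2(hull),
               tolerance = 1e-6)

  ## disjoint region is an explicit error naming both geometries
  far <- calibrationArea(rbind(c(10, 10), c(11, 10), c(11, 11), c(10, 11)))
  expect_error(buildAccessibleArea(occ, 50, regions = far),
               "does not intersect")
})

test_that("bilinear resampling interpolates and clamps as declared", {
  ## constant layer stays constant
  cst <- envStack(list(a = matrix(3.5, 10, 10)), c(0, 10), 0.1)
  out <- resampleToGrid(cst, c(0.1, 9.9), 0.05, c(12, 12))
  expect_true(all(out@layers$a == 3.5))

  ## 2x2 layer [[0,1],[0,1]] sampled at its center -> 0.5
  two <- envStack(list(a = matrix(c(0, 0, 1, 1), 2, 2)), c(0, 2), 1)
  mid <- resampleToGrid(two, c(0.5, 1.5), 1, c(1, 1))
  expect_equal(mid@layers$a[1, 1], 0.5)

  ## down-then-up round trip: bilinear beats nearest-neighbour RMSE
  sm <- generateEnvStack(landscapeSpec(nRows = 40, nCols = 40,
                                       autocorrRange = 6, nLayers = 1,
                                       seed = 5))
  down <- resampleToGrid(sm, sm@origin, sm@cellSize * 2, c(20, 20))
  upB <- resampleToGrid(down, sm@origin, sm@cellSize, c(40, 40))
  downN <- resampleToGrid(sm, sm@origin, sm@cellSize * 2, c(20, 20),
                          categorical = "env_01")
  upN <- resampleToGrid(downN, sm@origin, sm@cellSize, c(40, 40),
                        categorical = "env_01")
  rmse <- function(a, b) sqrt(mean((a - b)^2, na.rm = TRUE))
  expect_lt(rmse(upB@layers[[1]], sm@layers[[1]]),
            rmse(upN@layers[[1]], sm@layers[[1]]))

  ## disjoint extents are an error
  expect_error(resampleToGrid(cst, c(50, 50), 0.1, c(5, 5)), "disjoint")
})

test_that("the Spearman filter retains a maximal uncorrelated set in input order", {
  s <- tinyStack(seed = 13, n = 30, nLayers = 5, rho = 0.92)
  ## duplicate layer pair: exactly one of the two survives
  dup <- envStack(c(s@layers, list(copy = s@layers[[3]])), s@origin,
                  s@cellSize)
  fDup <- correlationFilter(dup, threshold = 0.8)
  expect_true("env_03" %in% layerNames(fDup$stack))
  expect_false("copy" %in% layerNames(fDup$stack))

  ## the rho = 0.92 pair: the later-listed member is dropped at 0.8
  f <- correlationFilter(s, threshold = 0.8)
  expect_true("env_01" %in% layerNames(f$stack))
  expect_false("env_02" %in% layerNames(f$stack))

  ## all-pairs oracle: every retained pair satisfies |rho| < 0.8
  kept <- f$stack
  vals <- vapply(kept@layers, c, numeric(length(kept@layers[[1]])))
  rho <- cor(vals, method = "spearman")
  expect_true(all(abs(rho[upper.tri(rho)]) < 0.8))

  ## order stability: same input order, same retained set
  f2 <- correlationFilter(s, threshold = 0.8)
  expect_identical(layerNames(f$stack), layerNames(f2$stack))
})

test_that("variable sets select layers and police internal correlation", {
  s <- tinyStack(seed = 17, n = 30, nLayers = 5)
  sets <- buildVariableSets(s, list(A = c("env_01", "env_03"),
                                    B = c("env_01", "env_04")))
  expect_named(sets, c("A", "B"))
  expect_true(all(c("env_01", "env_03") %in% layerNames(sets$A)))
  expect_true("env_01" %in% layerNames(sets$B))
  expect_equal(sets$A@setId, "A")

  ## a correlated pair inside a set: error or auto-filter by flag
  expect_error(buildVariableSets(s, list(C = c("env_01", "env_02"))),
               "correlated")
  auto <- buildVariableSets(s, list(C = c("env_01", "env_02")),
                            autoFilter = TRUE)
  expect_equal(layerNames(auto$C), "env_01")

  expect_error(buildVariableSets(s, list(D = character(0))), "empty")
  expect_error(buildVariableSets(s, list(E = "nope")), "nope")
})
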