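## Independent oracles used across the suite. Each is a deliberately naive
## implementation (enumeration, brute force, closed form) kept separate from
## the package's own code paths.

## Moran's I with rook neighbours, equal weights.
moranIOracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; w <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr) { num <- num + 2 * z[i, j] * z[i + 1, j]; w <- w + 2 }
    if (j < nc) { num <- num + 2 * z[i, j] * z[i, j + 1]; w <- w + 2 }
  }
  (length(m) / w) * num / sum(z^2)
}

## Single-season occupancy likelihood by brute-force enumeration of the
## latent occupancy vector z in {0,1}^S.
enumLogLikOracle <- function(y, psi, p) {
  nS <- nrow(y)
  total <- 0
  for (i in seq_len(nS)) {
    con <- !is.na(y[i, ])
    liteOcc <- prod(ifelse(y[i, con] == 1, p[i, con], 1 - p[i, con]))
    liteEmpty <- as.numeric(all(y[i, con] == 0))
    total <- total + log(psi[i] * liteOcc + (1 - psi[i]) * liteEmpty)
  }
  total
}

## Full 2^S marginalization (the "really brute force" variant, <= 10 sites).
enumLogLikFull <- function(y, psi, p) {
  nS <- nrow(y)
  stopifnot(nS <= 10)
  zGrid <- as.matrix(expand.grid(rep(list(c(0, 1)), nS)))
  lik <- 0
  for (r in seq_len(nrow(zGrid))) {
    z <- zGrid[r, ]
    pz <- prod(ifelse(z == 1, psi, 1 - psi))
    py <- 1
    for (i in seq_len(nS)) {
      con <- !is.na(y[i, ])
      pDet <- z[i] * p[i, con]
      py <- py * prod(ifelse(y[i, con] == 1, pDet, 1 - pDet))
    }
    lik <- lik + pz * py
  }
  log(lik)
}

## Exhaustive grid-search minimizer of the penalized maxent loss (2 features).
maxentGridOracle <- function(Fpres, Fbg, beta, grid = seq(-3, 3, 0.01)) {
  fbar <- colMeans(Fpres)
  best <- c(NA, NA); bestVal <- Inf
  for (l1 in grid) {
    eta1 <- Fbg[, 1] * l1
    for (l2 in grid) {
      eta <- eta1 + Fbg[, 2] * l2
      m <- max(eta)
      val <- -(fbar[1] * l1 + fbar[2] * l2) + m + log(sum(exp(eta - m))) +
        beta[1] * abs(l1) + beta[2] * abs(l2)
      if (val < bestVal) { bestVal <- val; best <- c(l1, l2) }
    }
  }
  best
}

## Random small detection dataset (with occasional missing surveys).
randomDetectionData <- function(nSites, nOcc, seed) {
  set.seed(seed)
  y <- matrix(rbinom(nSites * nOcc, 1, 0.4), nSites, nOcc)
  miss <- matrix(runif(nSites * nOcc) < 0.15, nSites, nOcc)
  for (i in seq_len(nSites))
    if (all(miss[i, ])) miss[i, sample(nOcc, 1)] <- FALSE
  y[miss] <- NA_integer_
  emptyStd <- data.frame(covariate = character(0), mean = numeric(0),
                         sd = numeric(0))
  new("DetectionData", y = y,
      siteCovariates = data.frame(row.names = seq_len(nSites)),
      surveyCovariates = list(), standardization = emptyStd)
}

## Intercept-only DetectionData from a plain y matrix.
detectionDataFromY <- function(y) {
  storage.mode(y) <- "integer"
  new("DetectionData", y = y,
      siteCovariates = data.frame(row.names = seq_len(nrow(y))),
      surveyCovariates = list(),
      standardization = data.frame(covariate = character(0),
                                   mean = numeric(0), sd = numeric(0)))
}

## Tiny landscape used in several tests.
tinyStack <- function(seed = 1, n = 40, nLayers = 4, rho = 0.92,
                      range = 4) {
  generateEnvStack(landscapeSpec(nRows = n, nCols = n, autocorrRange = range,
                                 nLayers = nLayers, correlatedPairRho = rho,
                                 seed = seed))
}
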