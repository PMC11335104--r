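## Synthetic-data module: spatially autocorrelated covariate rasters, biased
## occurrence samples from a known Gibbs surface, and Bernoulli detection
## histories with known ground truth. Everything downstream is testable
## against these generators without any external data.

#' Specification of a synthetic landscape
#'
#' Describes the raster grid and the random-field structure of a synthetic
#' study region. Defaults emulate a tropical-Andean study area: a grid of
#' roughly 1-km cells (0.01 degrees) with six environmental layers, of which
#' layers 1 and 2 form a highly correlated pair (Pearson r = 0.92), mimicking
#' ground-level versus atmospheric temperature products.
#'
#' @param nRows,nCols grid size in cells (>= 10)
#' @param cellSize cell size in decimal degrees (> 0)
#' @param origin (lon, lat) of the upper-left grid corner
#' @param autocorrRange correlation length of the random fields, in cells;
#'   must be < min(nRows, nCols)
#' @param nLayers number of environmental layers (>= 2 when a correlated
#'   pair is requested)
#' @param correlatedPairRho target Pearson correlation, in [-1, 1], between
#'   layers 1 and 2 (the designated pair)
#' @param seed integer RNG seed
#' @return a list of class "LandscapeSpec"
#' @export
landscapeSpec <- function(nRows = 100, nCols = 100, cellSize = 0.01,
                          origin = c(-75.8, 7.2), autocorrRange = 8,
                          nLayers = 6, correlatedPairRho = 0.92,
                          seed = 1L) {
  stopifnot(nRows >= 10, nCols >= 10, cellSize > 0,
            correlatedPairRho >= -1, correlatedPairRho <= 1,
            nLayers >= 1, autocorrRange > 0)
  structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                 cellSize = cellSize, origin = origin,
                 autocorrRange = autocorrRange, nLayers = as.integer(nLayers),
                 correlatedPairRho = correlatedPairRho,
                 seed = as.integer(seed)),
            class = "LandscapeSpec")
}

#' Ground-truth parameters of the synthetic data-generating process
#'
#' Houses the data-generating analogues of the quantities the pipeline
#' estimates: the feature weights of the generating Gibbs suitability
#' surface, the logit-scale occupancy (psi) and detection (p) coefficients
#' (intercept first), and the fraction of surveys not conducted.
#'
#' @param lambdaTrue feature weights of the Gibbs surface (one per layer
#'   used; linear features on the standardized layers)
#' @param betaPsiTrue occupancy coefficients, logit scale, intercept first
#' @param alphaPTrue detection coefficients, logit scale, intercept first
#' @param missingFraction proportion of surveys unconducted, in [0, 1)
#' @return a list of class "TruthParams"
#' @export
truthParams <- function(lambdaTrue = c(1.5, 0, -1, 0.5, 0, 0),
                        betaPsiTrue = qlogis(0.4),
                        alphaPTrue = qlogis(0.6),
                        missingFraction = 5 / 150) {
  stopifnot(all(is.finite(lambdaTrue)), all(is.finite(betaPsiTrue)),
            all(is.finite(alphaPTrue)),
            missingFraction >= 0, missingFraction < 1)
  structure(list(lambdaTrue = lambdaTrue, betaPsiTrue = betaPsiTrue,
                 alphaPTrue = alphaPTrue, missingFraction = missingFraction),
            class = "TruthParams")
}

## One smoothed Gaussian random field, standardized to mean 0 / sd 1.
## White noise on a padded grid multiplied by dense Gaussian smoothing
## matrices (separable kernel); deterministic given the RNG state.
gaussianRandomField <- function(nr, nc, range) {
  pad <- ceiling(3 * range)
  w <- matrix(rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad)
  smoother <- function(nOut, nIn) {
    d <- outer(seq_len(nOut) + pad, seq_len(nIn), `-`)
    k <- exp(-d^2 / (2 * range^2))
    k / rowSums(k)
  }
  f <- smoother(nr, nr + 2 * pad) %*% w %*% t(smoother(nc, nc + 2 * pad))
  (f - mean(f)) / sd(f)
}

#' Generate a stack of spatially autocorrelated environmental layers
#'
#' Each layer is a smoothed Gaussian random field standardized to mean 0,
#' sd 1. Layers 1 and 2 (the designated pair) are mixed so their empirical
#' Pearson correlation equals \code{correlatedPairRho}: the second field is
#' residualized against the first (empirical Gram-Schmidt) and recombined as
#' rho * a + sqrt(1 - rho^2) * resid, which realizes the target exactly.
#'
#' @param spec a [landscapeSpec()]
#' @return an [EnvStack-class] with layers env_01, env_02, ...
#' @export
generateEnvStack <- function(spec) {
  stopifnot(inherits(spec, "LandscapeSpec"))
  if (spec$autocorrRange >= min(spec$nRows, spec$nCols))
    stop("autocorrRange must be smaller than the grid: the field would be ",
         "essentially constant")
  set.seed(spec$seed)
  nr <- spec$nRows; nc <- spec$nCols
  fields <- lapply(seq_len(spec$nLayers), function(i)
    gaussianRandomField(nr, nc, spec$autocorrRange))
  if (spec$nLayers >= 2) {
    a <- fields[[1]]; b <- fields[[2]]
    resid <- b - cor(c(a), c(b)) * a        # empirical Gram-Schmidt
    resid <- (resid - mean(resid)) / sd(resid)
    rho <- spec$correlatedPairRho
    mixed <- rho * a + sqrt(1 - rho^2) * resid
    fields[[2]] <- (mixed - mean(mixed)) / sd(mixed)
  }
  names(fields) <- sprintf("env_%02d", seq_len(spec$nLayers))
  envStack(fields, spec$origin, spec$cellSize,
           nodataMask = matrix(FALSE, nr, nc))
}

## Raw Gibbs suitability over the valid cells of a stack: exp(sum lambda_k *
## layer_k), normalized to sum to 1. lambdaTrue is recycled/truncated to the
## number of layers.
gibbsSuitability <- function(stack, lambdaTrue) {
  idx <- validCells(stack)
  lam <- rep_len(lambdaTrue, length(stack@layers))
  lin <- numeric(length(idx))
  for (k in seq_along(stack@layers))
    lin <- lin + lam[k] * stack@layers[[k]][idx]
  p <- exp(lin - logSumExp(lin))
  list(idx = idx, prob = p)
}

#' Sample presence-only occurrence records biased toward high suitability
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' raw Gibbs suitability implied by \code{truth$lambdaTrue} times
#' exp(biasStrength * bias field), where the bias field is itself a smooth
#' random field standing in for accessibility bias. Records are returned at
#' cell-center coordinates with source tag "synthetic".
#'
#' @param stack an [EnvStack-class]
#' @param truth a [truthParams()]
#' @param n number of records (>= 1)
#' @param biasStrength nonnegative multiplier of the bias field
#' @param seed integer RNG seed
#' @return an [OccurrenceSet-class] with exactly n records
#' @export
sampleOccurrences <- function(stack, truth, n, biasStrength = 0, seed = 1L) {
  stopifnot(inherits(truth, "TruthParams"), n >= 1, biasStrength >= 0)
  g <- gibbsSuitability(stack, truth$lambdaTrue)
  if (!length(g$idx)) stop("all suitability mass is on nodata cells")
  set.seed(seed)
  w <- g$prob
  if (biasStrength > 0) {
    d <- dim(stack@layers[[1]])
    bias <- gaussianRandomField(d[1], d[2], max(2, min(d) %/% 10))
    w <- w * exp(biasStrength * bias[g$idx])
  }
  if (!any(w > 0)) stop("all suitability mass is on nodata cells")
  pick <- sample(g$idx, n, replace = TRUE, prob = w)
  xy <- cellCenters(stack, pick)
  occurrenceSet(xy[, "lon"], xy[, "lat"], source = "synthetic")
}

#' Simulate single-season detection histories with known ground truth
#'
#' Latent occupancy z_i ~ Bernoulli(psi_i) with logit(psi_i) = x_i' beta;
#' detections y_ij ~ Bernoulli(z_i * p_ij) with logit(p_ij) = w_ij' alpha.
#' A fraction of surveys is marked unconducted (NA) uniformly at random,
#' re-drawn (deterministically under the seed) until every site keeps at
#' least one conducted survey. Covariates are standardized (mean 0, sd 1)
#' and the standardization record stored on the returned object.
#'
#' @param siteCov data.frame of site covariates (nSites rows) in natural
#'   units, or NULL for intercept-only occupancy
#' @param surveyCov named list of nSites x nOccasions matrices in natural
#'   units, or NULL for intercept-only detection
#' @param truth a [truthParams()]; betaPsiTrue must have length
#'   1 + ncol(siteCov), alphaPTrue length 1 + length(surveyCov)
#' @param nSites,nOccasions dimensions of the detection matrix
#' @param seed integer RNG seed
#' @return a [DetectionData-class]
#' @export
simulateDetectionHistories <- function(siteCov = NULL, surveyCov = NULL,
                                       truth = truthParams(),
                                       nSites = 30, nOccasions = 5,
                                       seed = 1L) {
  stopifnot(inherits(truth, "TruthParams"))
  if (!is.null(siteCov)) stopifnot(nrow(siteCov) == nSites)
  if (!is.null(surveyCov))
    for (m in surveyCov) stopifnot(all(dim(m) == c(nSites, nOccasions)))
  nSiteCov <- if (is.null(siteCov)) 0 else ncol(siteCov)
  nSurvCov <- if (is.null(surveyCov)) 0 else length(surveyCov)
  stopifnot(length(truth$betaPsiTrue) == 1 + nSiteCov,
            length(truth$alphaPTrue) == 1 + nSurvCov)
  set.seed(seed)
  X <- cbind(1, if (nSiteCov) scale(as.matrix(siteCov)))
  psi <- plogis(drop(X %*% truth$betaPsiTrue))
  eta <- matrix(truth$alphaPTrue[1], nSites, nOccasions)
  scaledSurvey <- list()
  if (nSurvCov) for (k in seq_len(nSurvCov)) {
    m <- surveyCov[[k]]
    ms <- (m - mean(m, na.rm = TRUE)) / sd(c(m), na.rm = TRUE)
    scaledSurvey[[names(surveyCov)[k]]] <- ms
    eta <- eta + truth$alphaPTrue[1 + k] * ms
  }
  p <- plogis(eta)
  z <- rbinom(nSites, 1, psi)
  y <- matrix(rbinom(nSites * nOccasions, 1, rep(z, nOccasions) * c(p)),
              nSites, nOccasions)
  nMissing <- round(truth$missingFraction * nSites * nOccasions)
  if (nMissing > 0) {
    repeat {
      miss <- sample(nSites * nOccasions, nMissing)
      keep <- matrix(TRUE, nSites, nOccasions); keep[miss] <- FALSE
      if (all(rowSums(keep) >= 1)) break
    }
    y[miss] <- NA_integer_
  }
  std <- data.frame(covariate = character(0), mean = numeric(0),
                    sd = numeric(0), stringsAsFactors = FALSE)
  siteStd <- data.frame(row.names = seq_len(nSites))
  if (nSiteCov) {
    sc <- scale(as.matrix(siteCov))
    siteStd <- as.data.frame(sc)
    names(siteStd) <- names(siteCov)
    std <- rbind(std, data.frame(covariate = names(siteCov),
                                 mean = attr(sc, "scaled:center"),
                                 sd = attr(sc, "scaled:scale")))
  }
  if (nSurvCov) {
    std <- rbind(std, data.frame(
      covariate = names(surveyCov),
      mean = vapply(surveyCov, function(m) mean(m, na.rm = TRUE), 0),
      sd = vapply(surveyCov, function(m) sd(c(m), na.rm = TRUE), 0)))
  }
  rownames(std) <- NULL
  new("DetectionData", y = y, siteCovariates = siteStd,
      surveyCovariates = scaledSurvey, standardization = std)
}
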