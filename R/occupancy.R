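## Single-season occupancy modelling with imperfect detection. The site
## likelihood marginalizes the latent occupancy state:
##   L_i = psi_i * prod_j p_ij^y_ij (1-p_ij)^(1-y_ij) + (1-psi_i) * 1{no det}
## with logit-linear psi (site covariates) and p (survey or site covariates);
## unconducted surveys (NA) contribute nothing. AICc uses n = number of sites.

## Design matrices for one model. p covariates may live in surveyCovariates
## (site x occasion matrices) or siteCovariates (replicated across occasions).
occDesign <- function(data, psiCovariates, pCovariates) {
  y <- data@y
  nS <- nrow(y); nJ <- ncol(y)
  for (nm in psiCovariates)
    if (!nm %in% names(data@siteCovariates))
      stop("psi covariate '", nm, "' not found in siteCovariates")
  X <- cbind(rep(1, nS),
             if (length(psiCovariates))
               as.matrix(data@siteCovariates[psiCovariates]))
  colnames(X) <- c("(Intercept)", psiCovariates)
  W <- list(matrix(1, nS, nJ))
  for (nm in pCovariates) {
    W[[length(W) + 1]] <- if (nm %in% names(data@surveyCovariates)) {
      data@surveyCovariates[[nm]]
    } else if (nm %in% names(data@siteCovariates)) {
      matrix(data@siteCovariates[[nm]], nS, nJ)
    } else stop("p covariate '", nm, "' not found")
  }
  names(W) <- c("(Intercept)", pCovariates)
  if (any(!is.finite(X)))
    stop("non-finite psi covariate values")
  conducted <- !is.na(y)
  for (w in W) if (any(!is.finite(w[conducted])))
    stop("non-finite p covariate values at conducted surveys")
  list(X = X, W = W, conducted = conducted,
       noDetection = rowSums(y == 1, na.rm = TRUE) == 0)
}

## Log-likelihood and analytic gradient at theta = c(betaPsi, alphaP).
occLogLikCore <- function(theta, y, des, gradient = FALSE) {
  kb <- ncol(des$X)
  beta <- theta[seq_len(kb)]; alpha <- theta[-seq_len(kb)]
  psi <- plogis(drop(des$X %*% beta))
  etaP <- matrix(0, nrow(y), ncol(y))
  for (k in seq_along(des$W)) etaP <- etaP + alpha[k] * des$W[[k]]
  p <- plogis(etaP)
  con <- des$conducted
  logTerm <- ifelse(con, ifelse(!is.na(y) & y == 1, log(p), log1p(-p)), 0)
  logTerm[!con] <- 0
  logA <- rowSums(logTerm)
  A <- exp(logA)
  L <- psi * A + (1 - psi) * des$noDetection
  ll <- sum(log(L))
  if (!gradient) return(ll)
  dpsi <- psi * (1 - psi)
  gBeta <- drop(crossprod(des$X, (A - des$noDetection) * dpsi / L))
  resid <- (y - p)
  resid[!con] <- 0
  siteFac <- psi * A / L
  gAlpha <- vapply(des$W, function(w)
    sum(siteFac * rowSums(resid * w, na.rm = TRUE)), 0)
  list(ll = ll, grad = c(gBeta, unname(gAlpha)))
}

#' Single-season occupancy log-likelihood
#'
#' Marginalizes the latent occupancy state site by site; missing occasions
#' contribute nothing. Covariates are taken from the (standardized) tables
#' on the data object.
#'
#' @param data a [DetectionData-class]
#' @param betaPsi occupancy coefficients, logit scale, intercept first
#' @param alphaP detection coefficients, logit scale, intercept first
#' @param psiCovariates,pCovariates covariate names (empty: intercept-only)
#' @return the log-likelihood (a scalar)
#' @export
occupancyLogLik <- function(data, betaPsi, alphaP,
                            psiCovariates = character(0),
                            pCovariates = character(0)) {
  des <- occDesign(data, psiCovariates, pCovariates)
  stopifnot(length(betaPsi) == ncol(des$X),
            length(alphaP) == length(des$W))
  occLogLikCore(c(betaPsi, alphaP), data@y, des)
}

#' Maximum-likelihood fit of a single-season occupancy model
#'
#' Quasi-Newton (BFGS with analytic gradient) from zero-initialized
#' coefficients plus seeded jittered restarts, keeping the best optimum;
#' occupancy likelihoods are multimodal in small samples. Fits with
#' unbounded estimates (|coefficient| > 15, complete separation) or failed
#' convergence are returned flagged rather than as errors, so callers can
#' exclude them from model tables.
#'
#' @param data a [DetectionData-class]
#' @param pCovariates,psiCovariates covariate names for each linear predictor
#' @param nStarts number of optimizer starts (first is zero-initialized)
#' @param seed seed for the restart jitter
#' @return an [OccupancyFit-class]
#' @export
fitOccupancy <- function(data, pCovariates = character(0),
                         psiCovariates = character(0), nStarts = 5,
                         seed = 1L) {
  des <- occDesign(data, psiCovariates, pCovariates)
  y <- data@y
  if (ncol(y) < 2 || all(rowSums(des$conducted) < 2))
    warning("fewer than two occasions everywhere: psi and p are not separable")
  kb <- ncol(des$X); ka <- length(des$W)
  nll <- function(th) -occLogLikCore(th, y, des)
  gr <- function(th) -occLogLikCore(th, y, des, gradient = TRUE)$grad
  set.seed(seed)
  starts <- c(list(numeric(kb + ka)),
              lapply(seq_len(max(0, nStarts - 1)), function(i)
                rnorm(kb + ka, 0, 0.5)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, nll, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- best$par
  ll <- -best$value
  K <- kb + ka
  noDet <- all(y == 0 | is.na(y))
  unbounded <- any(abs(theta) > 15)
  vc <- matrix(NA_real_, K, K)
  converged <- best$convergence == 0 && !unbounded && !noDet
  if (converged) {
    h <- tryCatch(optimHess(theta, nll, gr), error = function(e) NULL)
    if (!is.null(h)) {
      vc <- tryCatch(solve(h), error = function(e) matrix(NA_real_, K, K))
      if (!anyNA(vc) && any(diag(vc) <= 0)) converged <- FALSE
    } else converged <- FALSE
  }
  nSites <- nrow(y)
  new("OccupancyFit",
      betaPsi = setNames(theta[seq_len(kb)], colnames(des$X)),
      alphaP = setNames(theta[kb + seq_len(ka)], names(des$W)),
      psiCovariates = psiCovariates, pCovariates = pCovariates,
      logLik = ll, K = K, aicc = aiccValue(ll, K, nSites), nSites = nSites,
      vcov = vc, standardization = data@standardization,
      converged = converged)
}

#' Model-comparison table from occupancy fits
#'
#' Rows sorted ascending by AICc with Akaike deltas, weights and cumulative
#' weights; non-converged fits are excluded.
#'
#' @param fits list of [OccupancyFit-class] objects
#' @return data.frame(label, K, aicc, deltaAicc, aiccWeight,
#'   cumulativeWeight)
#' @export
buildModelTable <- function(fits) {
  fits <- Filter(function(f) f@converged && is.finite(f@aicc), fits)
  if (!length(fits)) stop("no converged fit to tabulate")
  tab <- akaikeTable(vapply(fits, function(f) f@aicc, 0),
                     vapply(fits, modelLabel, ""))
  tab$K <- vapply(fits, function(f) f@K, 0)[match(tab$label,
                                            vapply(fits, modelLabel, ""))]
  tab[, c("label", "K", "aicc", "deltaAicc", "aiccWeight",
          "cumulativeWeight")]
}

#' Detection-first two-stage model selection
#'
#' Stage 1 fits p(candidate) psi(.) for every detection candidate and keeps
#' the minimum-AICc detection structure; stage 2 fixes that detection
#' structure and fits psi(candidate) for every occupancy candidate. Each
#' candidate is a character vector of covariate names (use character(0) for
#' an intercept-only structure); candidates are limited to
#' \code{maxCovariates} variables each.
#'
#' @param data a [DetectionData-class]
#' @param detectionCandidates,occupancyCandidates lists of covariate sets
#' @param maxCovariates per-candidate covariate cap (default 2)
#' @param nStarts,seed passed to [fitOccupancy()]
#' @return list(bestDetection, stage1Table, stage2Table, fits, bestFit)
#' @export
twoStageSelection <- function(data, detectionCandidates,
                              occupancyCandidates, maxCovariates = 2,
                              nStarts = 5, seed = 1L) {
  stopifnot(length(detectionCandidates) >= 1,
            length(occupancyCandidates) >= 1)
  for (cand in c(detectionCandidates, occupancyCandidates))
    if (length(cand) > maxCovariates)
      stop("candidate {", paste(cand, collapse = ","),
           "} exceeds the ", maxCovariates, "-covariate limit")
  stage1 <- lapply(detectionCandidates, function(cand)
    fitOccupancy(data, pCovariates = cand, nStarts = nStarts, seed = seed))
  ok1 <- Filter(function(f) f@converged && is.finite(f@aicc), stage1)
  if (!length(ok1)) stop("all detection-stage fits failed or diverged")
  tab1 <- buildModelTable(stage1)
  best1 <- ok1[[which.min(vapply(ok1, function(f) f@aicc, 0))]]
  bestDetection <- best1@pCovariates
  stage2 <- lapply(occupancyCandidates, function(cand)
    fitOccupancy(data, pCovariates = bestDetection, psiCovariates = cand,
                 nStarts = nStarts, seed = seed))
  tab2 <- buildModelTable(stage2)
  ok2 <- Filter(function(f) f@converged && is.finite(f@aicc), stage2)
  bestFit <- ok2[[which.min(vapply(ok2, function(f) f@aicc, 0))]]
  list(bestDetection = bestDetection, stage1Table = tab1,
       stage2Table = tab2, fits = stage2, bestFit = bestFit)
}

## Fitted psi and p for a fit on a dataset (same covariate structure).
occFitted <- function(fit, data) {
  des <- occDesign(data, fit@psiCovariates, fit@pCovariates)
  psi <- plogis(drop(des$X %*% fit@betaPsi))
  etaP <- matrix(0, nrow(data@y), ncol(data@y))
  for (k in seq_along(des$W)) etaP <- etaP + fit@alphaP[k] * des$W[[k]]
  list(psi = psi, p = plogis(etaP), conducted = des$conducted)
}

## MacKenzie-Bailey chi-squared discrepancy on detection-history
## frequencies. Sites are grouped into cohorts by missingness pattern;
## within each cohort the expected count of every possible history is
## accumulated over sites, observed histories contribute (O-E)^2/E, and the
## unobserved remainder contributes its pooled expectation.
mbChiSq <- function(fit, data) {
  fv <- occFitted(fit, data)
  y <- data@y
  pattern <- apply(fv$conducted, 1, paste, collapse = "")
  total <- 0
  for (pat in unique(pattern)) {
    sites <- which(pattern == pat)
    occ <- which(fv$conducted[sites[1], ])
    nJ <- length(occ)
    if (nJ > 20) stop("too many occasions to enumerate histories")
    hist <- as.matrix(expand.grid(rep(list(c(0, 1)), nJ)))
    obsKey <- apply(y[sites, occ, drop = FALSE], 1, paste, collapse = "")
    histKey <- apply(hist, 1, paste, collapse = "")
    E <- numeric(nrow(hist))
    for (i in sites) {
      pi <- fv$p[i, occ]
      probs <- apply(hist, 1, function(h)
        prod(ifelse(h == 1, pi, 1 - pi)))
      probs <- fv$psi[i] * probs +
        (1 - fv$psi[i]) * (rowSums(hist) == 0)
      E <- E + probs
    }
    O <- as.numeric(table(factor(obsKey, levels = histKey)))
    seen <- O > 0
    total <- total + sum((O[seen] - E[seen])^2 / E[seen]) + sum(E[!seen])
  }
  total
}

## Simulate a dataset from a fitted model, preserving the missingness
## pattern and covariates of the observed data.
simulateFromFit <- function(fit, data) {
  fv <- occFitted(fit, data)
  nS <- nrow(data@y); nJ <- ncol(data@y)
  z <- rbinom(nS, 1, fv$psi)
  y <- matrix(rbinom(nS * nJ, 1, rep(z, nJ) * c(fv$p)), nS, nJ)
  y[!fv$conducted] <- NA_integer_
  new("DetectionData", y = y, siteCovariates = data@siteCovariates,
      surveyCovariates = data@surveyCovariates,
      standardization = data@standardization)
}

#' Parametric-bootstrap goodness of fit (MacKenzie-Bailey chi-squared)
#'
#' Simulates \code{nSim} datasets from the fitted model (respecting the
#' observed missingness pattern), refits the same model structure to each
#' (two starts: the fitted values and zero, keeping the better optimum, so
#' the simulated fits mirror the observed one), and compares the observed
#' chi-squared history-frequency discrepancy with its simulated null
#' distribution. p = (1 + #\{T_s >= T_obs\}) / (nSim + 1).
#'
#' @param fit a converged [OccupancyFit-class]
#' @param data the [DetectionData-class] the fit was estimated on
#' @param nSim number of bootstrap simulations (default 1000)
#' @param seed integer RNG seed
#' @return list(statistic = T_obs, pval, simulated = T_s vector)
#' @export
parametricBootstrapGOF <- function(fit, data, nSim = 1000, seed = 1L) {
  if (!fit@converged) stop("goodness of fit requires a converged fit")
  tObs <- mbChiSq(fit, data)
  des <- occDesign(data, fit@psiCovariates, fit@pCovariates)
  theta0 <- c(fit@betaPsi, fit@alphaP)
  set.seed(seed)
  tSim <- rep(NA_real_, nSim)
  for (s in seq_len(nSim)) {
    simData <- simulateFromFit(fit, data)
    desS <- occDesign(simData, fit@psiCovariates, fit@pCovariates)
    nll <- function(th) -occLogLikCore(th, simData@y, desS)
    gr <- function(th) -occLogLikCore(th, simData@y, desS,
                                      gradient = TRUE)$grad
    o <- NULL
    for (start in list(theta0, 0 * theta0)) {
      oi <- tryCatch(optim(start, nll, gr, method = "BFGS",
                           control = list(maxit = 300, reltol = 1e-10)),
                     error = function(e) NULL)
      if (!is.null(oi) && all(is.finite(oi$par)) &&
          (is.null(o) || oi$value < o$value)) o <- oi
    }
    if (is.null(o)) next
    refit <- fit
    kb <- length(fit@betaPsi)
    refit@betaPsi[] <- o$par[seq_len(kb)]
    refit@alphaP[] <- o$par[-seq_len(kb)]
    tSim[s] <- mbChiSq(refit, simData)
  }
  dropped <- sum(is.na(tSim))
  if (dropped > 0.1 * nSim)
    stop("more than 10% of bootstrap refits failed (", dropped, "/", nSim, ")")
  if (dropped) warning(dropped, " bootstrap refit(s) failed and were dropped")
  tSim <- tSim[!is.na(tSim)]
  list(statistic = tObs,
       pval = (1 + sum(tSim >= tObs)) / (length(tSim) + 1),
       simulated = tSim)
}

#' Occupancy prediction curve along one covariate
#'
#' Predicted occupancy with delta-method confidence limits (computed on the
#' logit scale from the observed-information covariance, then
#' back-transformed, so limits stay inside (0, 1)). The grid is given in
#' natural units and standardized internally using the record stored on the
#' fit; all other psi covariates are held at their (standardized) mean 0.
#'
#' @param fit an [OccupancyFit-class]
#' @param covariate name of a psi covariate of the fit
#' @param grid covariate values in natural units
#' @param level confidence level
#' @return data.frame(value, estimate, lower, upper)
#' @export
predictCurves <- function(fit, covariate, grid, level = 0.95) {
  if (!covariate %in% fit@psiCovariates)
    stop("'", covariate, "' is not a psi covariate of this fit")
  std <- fit@standardization
  i <- match(covariate, std$covariate)
  zx <- if (!is.na(i)) (grid - std$mean[i]) / std$sd[i] else grid
  kb <- length(fit@betaPsi)
  C <- matrix(0, length(grid), kb,
              dimnames = list(NULL, names(fit@betaPsi)))
  C[, "(Intercept)"] <- 1
  C[, covariate] <- zx
  eta <- drop(C %*% fit@betaPsi)
  est <- plogis(eta)
  Vb <- fit@vcov[seq_len(kb), seq_len(kb), drop = FALSE]
  if (anyNA(Vb)) {
    warning("singular information matrix: confidence limits omitted")
    return(data.frame(value = grid, estimate = est, lower = NA_real_,
                      upper = NA_real_))
  }
  se <- sqrt(pmax(0, rowSums((C %*% Vb) * C)))
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(value = grid, estimate = est,
             lower = plogis(eta - zq * se), upper = plogis(eta + zq * se))
}

#' Covariate value at which predicted occupancy crosses a threshold
#'
#' Inverts the single-covariate prediction curve: solves
#' logit(threshold) = beta0 + beta1 * z and destandardizes. Used to
#' cross-check an occupancy threshold against its habitat interpretation
#' (e.g. the vegetation height at which psi drops through the cut).
#'
#' @param fit an [OccupancyFit-class] whose psi structure includes
#'   \code{covariate}
#' @param covariate psi covariate name
#' @param threshold occupancy probability in (0, 1)
#' @return the covariate value in natural units
#' @export
psiThresholdCovariate <- function(fit, covariate, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  if (!covariate %in% fit@psiCovariates)
    stop("'", covariate, "' is not a psi covariate of this fit")
  slope <- fit@betaPsi[covariate]
  if (slope == 0) stop("zero slope: threshold not invertible")
  z <- (qlogis(threshold) - fit@betaPsi["(Intercept)"]) / slope
  std <- fit@standardization
  i <- match(covariate, std$covariate)
  unname(if (!is.na(i)) std$mean[i] + std$sd[i] * z else z)
}

#' Naive occupancy: fraction of sites with at least one detection
#'
#' Uncorrected for imperfect detection; only conducted surveys count.
#'
#' @param data a [DetectionData-class]
#' @return a proportion in [0, 1]
#' @export
naiveOccupancy <- function(data) {
  mean(rowSums(data@y == 1, na.rm = TRUE) > 0)
}
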