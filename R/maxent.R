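## Maximum-entropy niche-model core. Linear (l) and quadratic (q) features on
## background-rescaled covariates, an L1-penalized Gibbs log-likelihood
## minimized by an active-set Newton method, and candidate-grid fitting over
## regularization multipliers x feature classes x variable sets.

## Default per-feature L1 penalty scale as a function of presence count m:
## piecewise-linear interpolation of the published Maxent defaults for
## linear/quadratic features ((10, 1.0), (30, 0.2), (100, 0.05)), clamped
## outside the table. The effective penalty is regMultiplier * defaultBeta(m).
defaultBetaLQ <- function(m) {
  stats::approx(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05),
                xout = m, rule = 2)$y
}

#' Feature specification for a maxent model
#'
#' Computes the per-layer scaling bounds (min/max over the background
#' sample) that map each covariate to [0, 1], and records which feature
#' classes are in play.
#'
#' @param stack an [EnvStack-class]
#' @param classes "l" (linear), "q" (quadratic) or "lq" (both)
#' @param backgroundIds linear cell indices of the background sample
#' @return a list of class "FeatureSpec"
#' @export
makeFeatureSpec <- function(stack, classes = "lq",
                            backgroundIds = validCells(stack)) {
  stopifnot(classes %in% c("l", "q", "lq"))
  bounds <- vapply(stack@layers, function(l) {
    v <- l[backgroundIds]
    range(v, na.rm = TRUE)
  }, numeric(2))
  rownames(bounds) <- c("min", "max")
  flat <- colnames(bounds)[bounds["max", ] - bounds["min", ] == 0]
  if (length(flat))
    stop("constant layer(s) over the background: ",
         paste(flat, collapse = ", "))
  structure(list(classes = classes, bounds = bounds),
            class = "FeatureSpec")
}

#' Build the feature matrix for a set of cells
#'
#' Each layer is rescaled to [0, 1] by its background min/max (values beyond
#' the background range, as arise during projection, are clamped). Linear
#' features are the rescaled values, quadratic features their squares;
#' "lq" concatenates both. Columns are named l_<layer> / q_<layer>.
#'
#' @param stack an [EnvStack-class]
#' @param spec a [makeFeatureSpec()] result
#' @param cells linear cell indices (default: all valid cells)
#' @return numeric matrix, one row per cell
#' @export
makeFeatures <- function(stack, spec, cells = validCells(stack)) {
  stopifnot(inherits(spec, "FeatureSpec"))
  b <- spec$bounds
  scaled <- vapply(colnames(b), function(nm) {
    v <- (stack@layers[[nm]][cells] - b["min", nm]) /
         (b["max", nm] - b["min", nm])
    pmin(1, pmax(0, v))
  }, numeric(length(cells)))
  if (length(cells) == 1) scaled <- matrix(scaled, 1,
                                           dimnames = list(NULL, colnames(b)))
  out <- NULL
  if (spec$classes %in% c("l", "lq")) {
    l <- scaled; colnames(l) <- paste0("l_", colnames(b))
    out <- l
  }
  if (spec$classes %in% c("q", "lq")) {
    q <- scaled^2; colnames(q) <- paste0("q_", colnames(b))
    out <- if (is.null(out)) q else cbind(out, q)
  }
  out
}

## Active-set Newton minimizer of the penalized maxent loss
##   f(lambda) = -mean_presences(lambda . f) + log sum_bg exp(lambda . f)
##             + sum_j beta_j |lambda_j|.
## Coordinates enter the active set when their KKT condition is violated
## (|grad_j| > beta_j); within the active set full Newton steps with
## backtracking are taken, truncated at sign crossings. Converged when the
## subgradient optimality residual's sup-norm is < tol.
fitMaxentCore <- function(Fpres, Fbg, beta, tol = 1e-6, maxOuter = 200) {
  p <- ncol(Fbg)
  fbar <- colMeans(Fpres)
  lam <- numeric(p); sgn <- numeric(p); active <- integer(0)
  smooth <- function(l) {
    eta <- drop(Fbg %*% l); lz <- logSumExp(eta)
    q <- exp(eta - lz)
    list(val = -sum(fbar * l) + lz, q = q,
         grad = drop(crossprod(Fbg, q)) - fbar)
  }
  objective <- function(l) {
    eta <- drop(Fbg %*% l)
    -sum(fbar * l) + logSumExp(eta) + sum(beta * abs(l))
  }
  kktResidual <- function(g) {
    r <- pmax(0, abs(g) - beta)
    if (length(active)) r[active] <- abs(g[active] + beta[active] * sgn[active])
    r
  }
  for (outer in seq_len(maxOuter)) {
    s <- smooth(lam)
    res <- kktResidual(s$grad)
    if (max(res) < tol)
      return(list(lambda = lam, converged = TRUE, kkt = max(res),
                  iterations = outer))
    inactive <- setdiff(which(res >= tol), active)
    if (length(inactive)) {
      j <- inactive[which.max(res[inactive])]
      active <- c(active, j)
      sgn[j] <- -sign(s$grad[j])
    }
    for (inner in seq_len(60)) {
      s <- smooth(lam)
      ga <- s$grad[active] + beta[active] * sgn[active]
      if (max(abs(ga)) < tol / 2) break
      Fa <- Fbg[, active, drop = FALSE]
      gq <- drop(crossprod(Fa, s$q))
      H <- crossprod(Fa * sqrt(s$q)) - tcrossprod(gq)
      diag(H) <- diag(H) + 1e-10
      d <- tryCatch(solve(H, -ga), error = function(e) -ga)
      ## cap the step at the first sign crossing of a nonzero coordinate
      lamA <- lam[active]
      crossing <- lamA != 0 & sign(lamA + d) != sign(lamA) & d != 0
      tmax <- if (any(crossing)) min(-lamA[crossing] / d[crossing], 1) else 1
      f0 <- objective(lam)
      slope <- sum(ga * d)
      t <- tmax
      repeat {
        lamTry <- lam
        lamTry[active] <- lamA + t * d
        lamTry[abs(lamTry) < 1e-14] <- 0
        if (objective(lamTry) <= f0 + 1e-4 * t * slope || t < 1e-12) break
        t <- t / 2
      }
      lam <- lamTry
      drop0 <- active[lam[active] == 0]
      if (length(drop0)) active <- setdiff(active, drop0)
      if (length(active)) sgn[active] <- sign(lam[active])
      if (!length(active)) break
    }
  }
  list(lambda = lam, converged = FALSE, kkt = max(kktResidual(smooth(lam)$grad)),
       iterations = maxOuter)
}

#' Fit a maximum-entropy niche model
#'
#' Minimizes the regularized Gibbs log loss
#' \deqn{-\frac1m \sum_{presences} \lambda'f(x) +
#'       \log \sum_{background} e^{\lambda'f(x)} + \sum_j \beta_j|\lambda_j|}
#' with \eqn{\beta_j} = regMultiplier x the published default penalty for the
#' feature's class at the presence count m. The fitted model carries the log
#' normalization constant over the background and the entropy of the raw
#' distribution (used by the cloglog transform).
#'
#' @param features numeric feature matrix over cells (rows indexable by the
#'   id vectors below), e.g. from [makeFeatures()]
#' @param presenceIds row indices of presence cells (>= 5; duplicates allowed)
#' @param backgroundIds row indices of background cells
#' @param regMultiplier positive regularization multiplier
#' @param featureSpec optional [makeFeatureSpec()] result; stored so the
#'   model can be projected onto rasters later
#' @param setId variable-set label
#' @return a [MaxentModel-class]
#' @export
fitMaxent <- function(features, presenceIds, backgroundIds,
                      regMultiplier = 1, featureSpec = NULL,
                      setId = "set_1") {
  stopifnot(length(presenceIds) >= 5, regMultiplier > 0)
  Fpres <- features[presenceIds, , drop = FALSE]
  Fbg <- features[backgroundIds, , drop = FALSE]
  m <- nrow(Fpres)
  beta <- regMultiplier * rep(defaultBetaLQ(m), ncol(features))
  fit <- fitMaxentCore(Fpres, Fbg, beta)
  if (!fit$converged)
    stop("maxent optimizer failed to converge: KKT residual ",
         format(fit$kkt), " after ", fit$iterations, " outer iterations (",
         ncol(features), " features, m = ", m, ")")
  lam <- setNames(fit$lambda, colnames(features))
  eta <- drop(Fbg %*% lam)
  logZ <- logSumExp(eta)
  q <- exp(eta - logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  classes <- if (is.null(featureSpec)) {
    pre <- unique(substr(colnames(features), 1, 1))
    if (all(c("l", "q") %in% pre)) "lq" else pre[1]
  } else featureSpec$classes
  bounds <- if (is.null(featureSpec)) matrix(numeric(0), 2, 0)
            else featureSpec$bounds
  new("MaxentModel", lambda = lam, regMultiplier = regMultiplier,
      featureClasses = classes, scalingBounds = bounds,
      backgroundIds = as.integer(backgroundIds), logZ = logZ, entropyH = H,
      setId = setId, converged = TRUE)
}

#' Raw (Gibbs) suitability for rows of a feature matrix
#'
#' raw(x) = exp(lambda . f(x) - logZ); over the training background the raw
#' values sum to one.
#'
#' @param model a [MaxentModel-class]
#' @param features feature matrix with the model's columns
#' @return numeric vector of raw suitabilities
#' @export
predictRaw <- function(model, features) {
  if (ncol(features) != length(model@lambda))
    stop("feature dimension mismatch: model has ", length(model@lambda),
         ", features have ", ncol(features))
  exp(drop(features %*% model@lambda) - model@logZ)
}

#' Cloglog suitability in [0, 1]
#'
#' cloglog(x) = 1 - exp(-exp(H) * raw(x)) with H the entropy of the fitted
#' raw distribution; a monotone transform of raw output.
#'
#' @inheritParams predictRaw
#' @export
predictCloglog <- function(model, features) {
  1 - exp(-exp(model@entropyH) * predictRaw(model, features))
}

#' Project a fitted model onto a raster stack
#'
#' Rebuilds features from the model's stored feature specification (with
#' clamping to the background range) and returns a suitability grid.
#'
#' @param model a [MaxentModel-class] fitted with a featureSpec
#' @param stack an [EnvStack-class] carrying the model's layers
#' @param type "cloglog" or "raw"
#' @return a numeric matrix shaped like the stack's layers (NA at nodata)
#' @export
predictGrid <- function(model, stack, type = c("cloglog", "raw")) {
  type <- match.arg(type)
  if (!ncol(model@scalingBounds))
    stop("model carries no feature specification; fit with featureSpec=")
  spec <- structure(list(classes = model@featureClasses,
                         bounds = model@scalingBounds), class = "FeatureSpec")
  idx <- validCells(stack)
  feats <- makeFeatures(stack, spec, idx)
  v <- if (type == "raw") predictRaw(model, feats)
       else predictCloglog(model, feats)
  out <- matrix(NA_real_, nrow(stack@layers[[1]]), ncol(stack@layers[[1]]))
  out[idx] <- v
  out
}

#' Random train/test split of occurrence indices
#'
#' @param n number of occurrences
#' @param fraction test fraction (default 0.2: a 20 percent random partition
#'   held out for evaluation)
#' @param seed integer RNG seed
#' @return list(trainIds, testIds, fraction, seed) of class "DataSplit"
#' @export
makeDataSplit <- function(n, fraction = 0.2, seed = 1L) {
  stopifnot(n >= 2, fraction > 0, fraction < 1)
  set.seed(seed)
  test <- sort(sample(n, max(1, round(fraction * n))))
  structure(list(trainIds = setdiff(seq_len(n), test), testIds = test,
                 fraction = fraction, seed = as.integer(seed)),
            class = "DataSplit")
}

#' Fit the candidate grid: regularization x feature classes x variable sets
#'
#' One model per (regularization multiplier, feature-class label, variable
#' set) triple, all sharing the same train/test split of the occurrences.
#' Model ids follow the scheme M_<reg>_F_<features>_<set>. Individual fit
#' failures are recorded and skipped; only total failure is an error.
#'
#' @param occ an [OccurrenceSet-class] (already thinned)
#' @param sets named list of [EnvStack-class] variable sets (masked to the
#'   accessible area)
#' @param regValues numeric vector of regularization multipliers
#' @param featureLabels subset of c("l", "q", "lq")
#' @param split a [makeDataSplit()] over the occurrences
#' @param backgroundMax background sample cap (uniform random sample beyond)
#' @param seed seed for the background sample
#' @return list of candidates, each
#'   list(id, model, set, reg, features, trainCells, testCells, error)
#' @export
runCandidateGrid <- function(occ, sets, regValues = c(0.1, 0.5, 1, 2, 5),
                             featureLabels = c("l", "q", "lq"),
                             split = makeDataSplit(nRecords(occ)),
                             backgroundMax = 10000, seed = 1L) {
  stopifnot(length(regValues) >= 1, length(featureLabels) >= 1,
            length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("set_", seq_along(sets))
  r <- occ@records
  out <- list()
  for (sid in names(sets)) {
    stack <- sets[[sid]]
    d <- dim(stack@layers[[1]])
    cellOfRecord <- cellIndexOf(r$lon, r$lat, d[1], d[2], stack@origin,
                                stack@cellSize)
    usable <- !is.na(cellOfRecord) & !stack@nodataMask[cellOfRecord]
    if (!any(usable[split$trainIds]))
      stop("no training occurrence falls on a usable cell of ", sid)
    vc <- validCells(stack)
    if (length(vc) > backgroundMax) {
      set.seed(seed)
      vc <- sort(sample(vc, backgroundMax))
    }
    trainCells <- cellOfRecord[intersect(split$trainIds, which(usable))]
    testCells <- cellOfRecord[intersect(split$testIds, which(usable))]
    for (feat in featureLabels) {
      spec <- makeFeatureSpec(stack, feat, vc)
      allCells <- c(vc, trainCells, testCells)
      feats <- makeFeatures(stack, spec, allCells)
      bgRows <- seq_along(vc)
      trRows <- length(vc) + seq_along(trainCells)
      for (reg in regValues) {
        id <- sprintf("M_%s_F_%s_%s", format(reg, trim = TRUE), feat, sid)
        cand <- tryCatch({
          model <- fitMaxent(feats, trRows, bgRows, reg, spec, sid)
          list(id = id, model = model, set = sid, reg = reg,
               features = feat, trainCells = trainCells,
               testCells = testCells, error = NULL)
        }, error = function(e)
          list(id = id, model = NULL, set = sid, reg = reg,
               features = feat, trainCells = trainCells,
               testCells = testCells, error = conditionMessage(e)))
        out[[id]] <- cand
      }
    }
  }
  failed <- vapply(out, function(c) is.null(c$model), TRUE)
  if (all(failed))
    stop("all candidate fits failed; first error: ", out[[1]]$error)
  out
}
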