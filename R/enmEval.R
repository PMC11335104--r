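## Candidate evaluation and selection: omission rate against the E-percent
## training-presence threshold, bootstrap partial ROC, AICc on the raw Gibbs
## output, joint selection criteria, median consensus, and binarization at
## the averaged 10th-percentile training-presence threshold.

#' Omission rate of test presences below the E-percent training threshold
#'
#' The threshold tau_E is the suitability value below which E percent of the
#' training presences fall (linear-interpolation quantile); the omission
#' rate is the percentage of test presences with suitability strictly below
#' tau_E.
#'
#' @param testSuit suitabilities at the test presences (non-empty)
#' @param trainSuit suitabilities at the training presences (non-empty)
#' @param E percentage in (0, 100)
#' @return omission rate in percent
#' @export
omissionRate <- function(testSuit, trainSuit, E = 5) {
  if (!length(trainSuit)) stop("empty training set")
  if (!length(testSuit)) stop("empty test set")
  tau <- unname(quantile(trainSuit, E / 100, type = 7))
  100 * mean(testSuit < tau)
}

#' Bootstrap partial ROC: AUC ratio over the high-sensitivity region
#'
#' For each bootstrap resample of the test presences (a fraction, with
#' replacement) the ROC curve of suitability against the background is
#' restricted to sensitivity >= 1 - E/100; the partial AUC of the model
#' curve is divided by the partial AUC of the chance diagonal over the same
#' proportion-of-area interval. A ratio above 1 indicates performance beyond
#' random expectation; the p-value is the fraction of bootstrap ratios <= 1.
#'
#' @param testSuit suitabilities at the test presences
#' @param bgSuit suitabilities over the background/calibration cells
#' @param E omission tolerance in percent
#' @param nBoot number of bootstrap iterations (>= 100)
#' @param bootFraction fraction of presences resampled each iteration
#' @param seed integer RNG seed
#' @return list(meanAucRatio, pval, ratios)
#' @export
partialROC <- function(testSuit, bgSuit, E = 5, nBoot = 500,
                       bootFraction = 0.5, seed = 1L) {
  stopifnot(nBoot >= 100, bootFraction > 0, bootFraction <= 1)
  if (length(unique(bgSuit)) < 2 || diff(range(c(testSuit, bgSuit))) == 0)
    stop("degenerate (constant) suitability: partial ROC undefined")
  thr <- sort(unique(bgSuit))
  if (length(thr) > 1500)
    thr <- unname(quantile(bgSuit, seq(0, 1, length.out = 1500), type = 7))
  xArea <- vapply(thr, function(t) mean(bgSuit >= t), 0)  # prop. area predicted
  sensMin <- 1 - E / 100
  ratioOf <- function(pres) {
    sens <- vapply(thr, function(t) mean(pres >= t), 0)
    keep <- sens >= sensMin
    if (sum(keep) < 2) return(NA_real_)
    x <- c(1, xArea[keep]); y <- c(1, sens[keep])   # t -> -Inf endpoint
    o <- order(x)
    x <- x[o]; y <- y[o]
    dx <- diff(x)
    aucModel <- sum(dx * (head(y, -1) + y[-1]) / 2)
    aucNull <- sum(dx * (head(x, -1) + x[-1]) / 2)
    if (aucNull == 0) return(NA_real_)
    aucModel / aucNull
  }
  set.seed(seed)
  nSub <- max(1, round(bootFraction * length(testSuit)))
  ratios <- vapply(seq_len(nBoot), function(b)
    ratioOf(sample(testSuit, nSub, replace = TRUE)), 0)
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) stop("partial ROC: no valid bootstrap ratio")
  list(meanAucRatio = mean(ratios), pval = mean(ratios <= 1),
       ratios = ratios)
}

#' AICc of a maxent model from its raw output
#'
#' The log-likelihood is the sum over presences of the log raw suitability
#' (the Gibbs probability normalized over all background cells); K is the
#' number of nonzero feature weights; the small-sample correction uses the
#' presence count n.
#'
#' @param model a [MaxentModel-class]
#' @param presenceFeatures feature matrix rows at the presence cells
#' @return list(aicc, K, logLik); aicc is NA (flagged) when n <= K + 1
#' @export
maxentAICc <- function(model, presenceFeatures) {
  raw <- predictRaw(model, presenceFeatures)
  ll <- sum(log(raw))
  K <- sum(model@lambda != 0)
  n <- nrow(presenceFeatures)
  list(aicc = aiccValue(ll, K, n), K = K, logLik = ll)
}

#' Evaluate every fitted candidate of a grid
#'
#' Computes, per candidate, the mean partial-ROC AUC ratio and p-value, the
#' omission rate at the E-percent training threshold, AICc on the raw
#' output, and the nonzero-weight count; deltas and Akaike weights are
#' computed across all candidates with defined AICc.
#'
#' @param candidates result of [runCandidateGrid()]
#' @param sets the named list of [EnvStack-class] variable sets used to fit
#' @param E omission/pROC tolerance in percent
#' @param nBoot,bootFraction,seed bootstrap settings for [partialROC()]
#' @return data.frame of candidate metrics (one row per fitted candidate)
#' @export
evaluateCandidates <- function(candidates, sets, E = 5, nBoot = 500,
                               bootFraction = 0.5, seed = 1L) {
  rows <- list()
  for (cand in candidates) {
    if (is.null(cand$model)) next
    model <- cand$model
    stack <- sets[[cand$set]]
    spec <- structure(list(classes = model@featureClasses,
                           bounds = model@scalingBounds),
                      class = "FeatureSpec")
    bgF <- makeFeatures(stack, spec, model@backgroundIds)
    trF <- makeFeatures(stack, spec, cand$trainCells)
    teF <- makeFeatures(stack, spec, cand$testCells)
    bgC <- predictCloglog(model, bgF)
    trC <- predictCloglog(model, trF)
    teC <- predictCloglog(model, teF)
    om <- omissionRate(teC, trC, E)
    pr <- tryCatch(partialROC(teC, bgC, E, nBoot, bootFraction, seed),
                   error = function(e) list(meanAucRatio = NA_real_,
                                            pval = NA_real_))
    ic <- maxentAICc(model, trF)
    rows[[cand$id]] <- data.frame(
      modelId = cand$id, meanAucRatio = pr$meanAucRatio, pvalProc = pr$pval,
      omissionRatePct = om, aicc = ic$aicc, numParameters = ic$K,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no fitted candidate to evaluate")
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  ok <- is.finite(m$aicc)
  m$deltaAicc <- NA_real_; m$aiccWeight <- NA_real_
  if (any(ok)) {
    m$deltaAicc[ok] <- m$aicc[ok] - min(m$aicc[ok])
    w <- exp(-m$deltaAicc[ok] / 2)
    m$aiccWeight[ok] <- w / sum(w)
  }
  m
}

#' Select candidates by the joint evaluation criteria
#'
#' Retains candidates with omission rate below \code{omissionMax} percent, a
#' mean AUC ratio above 1, and a significant partial ROC, then keeps, among
#' the retained, those within \code{deltaAiccMax} of the best retained AICc
#' (deltas recomputed within the retained set).
#'
#' @param metrics data.frame from [evaluateCandidates()]
#' @param omissionMax maximum omission rate in percent (default 5)
#' @param pvalMax partial-ROC significance cut (default 0.05)
#' @param deltaAiccMax AICc window among survivors (default 2)
#' @return character vector of selected model ids (empty, with a warning,
#'   when no candidate meets the criteria)
#' @export
selectModels <- function(metrics, omissionMax = 5, pvalMax = 0.05,
                         deltaAiccMax = 2) {
  stopifnot(nrow(metrics) >= 1)
  ok <- is.finite(metrics$aicc) &
    metrics$omissionRatePct < omissionMax &
    !is.na(metrics$meanAucRatio) & metrics$meanAucRatio > 1 &
    !is.na(metrics$pvalProc) & metrics$pvalProc < pvalMax
  if (!any(ok)) {
    warning("no model met the selection criteria")
    return(character(0))
  }
  sub <- metrics[ok, , drop = FALSE]
  delta <- sub$aicc - min(sub$aicc)
  sub$modelId[delta <= deltaAiccMax]
}

#' Cellwise median consensus of suitability grids
#'
#' @param grids list of aligned numeric matrices (>= 1); a cell is nodata in
#'   the consensus iff it is nodata in any input
#' @return a numeric matrix
#' @export
consensusMedian <- function(grids) {
  stopifnot(length(grids) >= 1)
  d <- dim(grids[[1]])
  for (g in grids)
    if (!identical(dim(g), d)) stop("misaligned grids")
  if (length(grids) == 1) return(grids[[1]])
  arr <- array(unlist(grids), dim = c(d, length(grids)))
  out <- apply(arr, c(1, 2), function(v)
    if (anyNA(v)) NA_real_ else median(v))
  out
}

#' E-percent training-presence threshold of one model
#'
#' The suitability value below which E percent of the training presences
#' fall (linear interpolation between order statistics). With the default
#' E = 10 this is the 10th-percentile training-presence threshold.
#'
#' @param trainSuit suitabilities at the training presences
#' @param E percentage
#' @export
trainingPresenceThreshold <- function(trainSuit, E = 10) {
  stopifnot(length(trainSuit) >= 1)
  unname(quantile(trainSuit, E / 100, type = 7))
}

#' Binarize a suitability grid at a threshold
#'
#' Cells with suitability >= threshold become 1, others 0; nodata is
#' preserved. For the pipeline the threshold is the mean over selected
#' models of each model's 10th-percentile training-presence threshold.
#'
#' @param grid numeric suitability matrix
#' @param threshold finite threshold
#' @param origin,cellSize geographic transform of the grid
#' @param provenance model ids the map derives from
#' @return a [BinaryMap-class]
#' @export
binarize <- function(grid, threshold, origin = c(0, 0), cellSize = 1,
                     provenance = character(0)) {
  stopifnot(is.finite(threshold))
  out <- ifelse(is.na(grid), NA_real_, as.numeric(grid >= threshold))
  new("BinaryMap", grid = out, origin = as.numeric(origin),
      cellSize = cellSize, threshold = threshold, provenance = provenance)
}
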