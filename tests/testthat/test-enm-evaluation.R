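test_that("omission rates follow the E-percent training threshold", {
  ## all test presences above the threshold -> 0 percent
  expect_equal(omissionRate(testSuit = c(0.5, 0.6, 0.9),
                            trainSuit = seq(0.3, 0.8, 0.1), E = 5), 0)
  ## empty sets are errors
  expect_error(omissionRate(numeric(0), 1:3), "test")
  expect_error(omissionRate(1:3, numeric(0)), "training")

  ## Monte-Carlo oracle: with random suitability, expected omission ~ E
  set.seed(31)
  reps <- vapply(seq_len(1000), function(i)
    omissionRate(runif(40), runif(60), E = 5), 0)
  expect_equal(mean(reps), 5, tolerance = 1)
})

test_that("partial ROC separates perfect, informative and null classifiers", {
  set.seed(5)
  bg <- runif(2000)
  ## perfect separation: ratio near its theoretical ceiling of 2
  perfect <- partialROC(testSuit = runif(60, 1.001, 1.2), bgSuit = bg,
                        E = 5, nBoot = 100, seed = 2)
  expect_gt(perfect$meanAucRatio, 1.9)
  expect_lte(perfect$meanAucRatio, 2 / (1 - 0.05))
  expect_equal(perfect$pval, 0)

  ## null: presences drawn from the background distribution
  null <- partialROC(testSuit = runif(60), bgSuit = bg, E = 5,
                     nBoot = 500, seed = 3)
  expect_equal(null$meanAucRatio, 1, tolerance = 0.1)
  expect_gt(null$pval, 0.1)
  expect_lt(null$pval, 0.9)
  ## proper proportion, nonnegative ratios
  expect_gte(null$pval, 0)
  expect_lte(null$pval, 1)
  expect_true(all(null$ratios >= 0))

  ## an informative classifier earns ratio > 1 on every bootstrap
  strong <- partialROC(testSuit = rbeta(60, 5, 1), bgSuit = bg, E = 5,
                       nBoot = 200, seed = 4)
  expect_true(all(strong$ratios > 1))
  expect_equal(strong$pval, 0)

  ## constant suitability is degenerate
  expect_error(partialROC(rep(0.5, 10), rep(0.5, 100)), "degenerate")
})

test_that("maxent AICc uses the raw likelihood, nonzero weights, and the small-sample correction", {
  ## uniform model over N background cells: logLik = -n log N exactly
  F <- cbind(l_a = runif(200), l_b = runif(200))
  m0 <- fitMaxent(F, sample(200, 54, replace = TRUE), seq_len(200), 1e6)
  ic <- maxentAICc(m0, F[seq_len(54), ])
  expect_equal(ic$logLik, -54 * log(200), tolerance = 1e-9)
  expect_equal(ic$K, 0)

  ## the correction term: K = 10, n = 54 adds 2*10*11/43 over plain AIC
  expect_equal(occuRange:::aiccValue(-100, 10, 54) - (2 * 10 + 200),
               2 * 10 * 11 / 43, tolerance = 1e-12)

  ## AICc ordering of two nested candidates matches the formula oracle
  set.seed(6)
  pres <- sample(200, 54, replace = TRUE, prob = exp(2 * F[, 1]))
  mA <- fitMaxent(F, pres, seq_len(200), 0.5)
  mB <- fitMaxent(F[, 1, drop = FALSE], pres, seq_len(200), 0.5)
  icA <- maxentAICc(mA, F[pres, ])
  icB <- maxentAICc(mB, F[pres, 1, drop = FALSE])
  oracle <- function(ll, K, n) 2 * K - 2 * ll + 2 * K * (K + 1) / (n - K - 1)
  expect_equal(icA$aicc, oracle(icA$logLik, icA$K, 54), tolerance = 1e-12)
  expect_equal(icB$aicc, oracle(icB$logLik, icB$K, 54), tolerance = 1e-12)

  ## n <= K + 1 flags AICc as undefined
  expect_true(is.na(occuRange:::aiccValue(-10, 10, 11)))
})

test_that("model selection applies the joint criteria and the AICc window", {
  metrics <- data.frame(
    modelId = c("M_0.5_F_lq_set_2", "M_0.6_F_lq_set_2", "M_0.3_F_lq_set_2",
                "M_0.7_F_lq_set_2", "M_1_F_l_set_1", "M_2_F_q_set_1"),
    meanAucRatio = c(1.787, 1.791, 1.777, 1.795, 0.99, 1.4),
    pvalProc = c(0, 0, 0, 0, 0.5, 0.2),
    omissionRatePct = c(0, 0, 0, 0, 0, 12),
    aicc = c(935.851, 936.684, 937.189, 937.527, 930, 1000),
    numParameters = c(10, 10, 12, 10, 3, 4))
  ## the four survivors share features/set and differ only in regularization
  sel <- selectModels(metrics)
  expect_setequal(sel, metrics$modelId[1:4])

  ## single passing candidate selects itself
  one <- metrics[2, , drop = FALSE]
  expect_equal(selectModels(one), "M_0.6_F_lq_set_2")

  ## nothing passes -> empty selection with an explicit message
  bad <- metrics
  bad$omissionRatePct <- 50
  expect_warning(out <- selectModels(bad), "no model met")
  expect_length(out, 0)
})

test_that("printed candidate-table arithmetic is reproduced", {
  ## AICc column of the four selected niche models
  aicc <- c(935.851, 936.684, 937.189, 937.527)
  tab <- akaikeTable(aicc)
  expect_equal(tab$deltaAicc, c(0, 0.833, 1.338, 1.676), tolerance = 0.002)
  ## weights from any AICc vector sum to one; min-AICc has delta 0 and the
  ## largest weight
  expect_equal(sum(tab$aiccWeight), 1, tolerance = 1e-9)
  expect_equal(tab$deltaAicc[1], 0)
  expect_equal(which.max(tab$aiccWeight), 1L)
  expect_equal(tab$cumulativeWeight[4], 1, tolerance = 1e-9)
})

test_that("median consensus matches a sort-based oracle cellwise", {
  ## single model -> identity
  g <- matrix(runif(16), 4)
  expect_identical(consensusMedian(list(g)), g)

  ## three grids, known middle value
  g1 <- matrix(0.2, 2, 2); g2 <- matrix(0.5, 2, 2); g3 <- matrix(0.9, 2, 2)
  expect_true(all(consensusMedian(list(g1, g2, g3)) == 0.5))

  ## even count: mean of the two central order statistics, plus nodata
  ## propagation from any input
  set.seed(8)
  grids <- lapply(1:4, function(i) matrix(runif(36), 6))
  grids[[2]][3, 3] <- NA
  cm <- consensusMedian(grids)
  for (i in 1:6) for (j in 1:6) {
    v <- vapply(grids, function(g) g[i, j], 0)
    expected <- if (anyNA(v)) NA_real_ else mean(sort(v)[2:3])
    expect_equal(cm[i, j], expected)
  }
  expect_error(consensusMedian(list(g, matrix(0, 3, 3))), "misaligned")
})

test_that("thresholding follows the 10th-percentile training-presence rule", {
  ## fixture whose per-model thresholds average to 0.096
  perModel <- c(0.08, 0.10, 0.10, 0.104)
  expect_equal(mean(perModel), 0.096)

  ## order-statistic check: the count strictly below the interpolated
  ## threshold is floor(0.1 n) or ceiling(0.1 n)
  set.seed(9)
  train <- runif(54)
  thr <- trainingPresenceThreshold(train, E = 10)
  expect_true(sum(train < thr) %in% c(floor(0.1 * 54), ceiling(0.1 * 54)))
  srt <- sort(train)
  expect_gte(thr, srt[floor(0.1 * 54)])
  expect_lte(thr, srt[ceiling(0.1 * 54) + 1])

  ## threshold 0 turns every non-nodata cell on; ties binarize to 1
  g <- matrix(runif(25), 5); g[1, 1] <- NA
  b0 <- binarize(g, 0)
  expect_equal(sum(b0@grid == 1, na.rm = TRUE), 24)
  expect_true(is.na(b0@grid[1, 1]))
  gTie <- matrix(c(0.3, 0.5, 0.7, 0.5), 2)
  expect_equal(sum(binarize(gTie, 0.5)@grid), 3)

  ## area is monotone non-increasing in the threshold
  areas <- vapply(seq(0, 1, 0.1), function(t)
    sum(binarize(g, t)@grid == 1, na.rm = TRUE), 0)
  expect_true(all(diff(areas) <= 0))
})
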