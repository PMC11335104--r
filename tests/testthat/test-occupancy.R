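test_that("the likelihood matches hand computation and the enumeration oracle", {
  ## single site, history [1,1], psi = p = 0.5 -> L = 0.5 * 0.25
  d11 <- detectionDataFromY(matrix(c(1, 1), 1, 2))
  expect_equal(occupancyLogLik(d11, qlogis(0.5), qlogis(0.5)), log(0.125))
  ## history [0,0] -> L = 0.5 * 0.25 + 0.5
  d00 <- detectionDataFromY(matrix(c(0, 0), 1, 2))
  expect_equal(occupancyLogLik(d00, qlogis(0.5), qlogis(0.5)), log(0.625))

  ## property: equals brute-force latent-state marginalization on random
  ## small datasets (with missing surveys)
  for (seed in 1:12) {
    nS <- sample(2:9, 1)
    nJ <- sample(2:5, 1)
    d <- randomDetectionData(nS, nJ, seed)
    beta <- rnorm(1); alpha <- rnorm(1)
    psi <- rep(plogis(beta), nS)
    p <- matrix(plogis(alpha), nS, nJ)
    ll <- occupancyLogLik(d, beta, alpha)
    expect_equal(ll, enumLogLikOracle(d@y, psi, p), tolerance = 1e-10)
    expect_equal(ll, enumLogLikFull(d@y, psi, p), tolerance = 1e-10)
  }
})

test_that("the MLE recovers known occupancy and detection parameters", {
  tr <- truthParams(betaPsiTrue = qlogis(0.4), alphaPTrue = qlogis(0.6),
                    missingFraction = 0)
  d <- simulateDetectionHistories(NULL, NULL, tr, 500, 6, seed = 21)
  f <- fitOccupancy(d)
  expect_true(f@converged)
  expect_equal(plogis(unname(f@betaPsi)), 0.4, tolerance = 0.05)
  expect_equal(plogis(unname(f@alphaP)), 0.6, tolerance = 0.05)
  ## AICc consistency: n = number of sites
  expect_equal(f@aicc, 2 * 2 - 2 * f@logLik + 2 * 2 * 3 / (500 - 3),
               tolerance = 1e-10)

  ## all-zero detection matrix is flagged, not an error
  dz <- detectionDataFromY(matrix(0L, 20, 4))
  fz <- fitOccupancy(dz)
  expect_false(fz@converged)
})

test_that("a negative occupancy slope is recovered with its sign", {
  ## ~50 quick replicates at 200 sites; the acceptance suite runs the
  ## full 200-replicate version
  hits <- 0
  for (r in 1:50) {
    siteCov <- data.frame(Veg_H = runif(200, 0.5, 5))
    tr <- truthParams(betaPsiTrue = c(0.2, -1), alphaPTrue = qlogis(0.55),
                      missingFraction = 0)
    d <- simulateDetectionHistories(siteCov, NULL, tr, 200, 4,
                                    seed = 100 + r)
    f <- fitOccupancy(d, psiCovariates = "Veg_H", nStarts = 2,
                      seed = r)
    if (f@converged && f@betaPsi[["Veg_H"]] < 0) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("model tables reproduce the printed detection and occupancy comparisons", {
  ## detection-stage table: five AICc values and their printed weights
  t2 <- akaikeTable(c(76.753, 79.696, 81.658, 82.961, 83.163),
                    c("p(N_obj) psi(.)", "p(Veg_H) psi(.)", "p(.) psi(.)",
                      "p(T_ground) psi(.)", "p(Soil_moisture) psi(.)"))
  expect_lt(max(abs(t2$aiccWeight -
                      c(0.714, 0.164, 0.061, 0.032, 0.029))), 0.002)
  expect_lt(max(abs(t2$deltaAicc - c(0, 2.943, 4.905, 6.207, 6.410))),
            0.002)
  expect_equal(t2$cumulativeWeight[5], 1, tolerance = 1e-9)

  ## occupancy-stage table: 16 models; best weight 0.324, runner-up 0.096
  aicc3 <- c(70.090, 72.517, 72.536, 72.615, 72.619, 72.647, 72.906,
             72.990, 76.321, 76.462, 77.409, 77.867, 78.269, 78.803,
             79.395, 89.356)
  t3 <- akaikeTable(aicc3)
  expect_lt(abs(t3$aiccWeight[1] - 0.324), 0.002)
  expect_lt(abs(t3$aiccWeight[2] - 0.096), 0.002)
  expect_true(all(diff(t3$cumulativeWeight) >= 0))

  ## single model: delta 0, weight 1
  t1 <- akaikeTable(50, "only")
  expect_equal(t1$aiccWeight, 1)
  expect_equal(t1$deltaAicc, 0)

  ## AICc arithmetic at the conventional design size: n = 30, K = 3
  expect_equal(occuRange:::aiccValue(-10, 3, 30) - (2 * 3 + 20),
               24 / 26, tolerance = 1e-12)

  ## ties sort stably by label
  tie <- akaikeTable(c(10, 10, 9), c("b", "a", "c"))
  expect_identical(tie$label, c("c", "a", "b"))
})

test_that("estimated occupancy exceeds naive occupancy on average when detection is imperfect", {
  tr <- truthParams(betaPsiTrue = qlogis(0.4), alphaPTrue = qlogis(0.45),
                    missingFraction = 0)
  psiHat <- naive <- rep(NA_real_, 30)
  for (r in 1:30) {
    d <- simulateDetectionHistories(NULL, NULL, tr, 100, 4, seed = 700 + r)
    f <- fitOccupancy(d, nStarts = 2, seed = r)
    if (!f@converged) next
    psiHat[r] <- plogis(unname(f@betaPsi))
    naive[r] <- naiveOccupancy(d)
  }
  ok <- !is.na(psiHat)
  expect_gte(sum(ok), 25)
  expect_gt(mean(psiHat[ok]), mean(naive[ok]))
})

test_that("detection-first two-stage selection finds the true detection covariate", {
  ## p truly depends on one survey covariate; stage 1 should pick it up in
  ## most replicates (20 quick replicates here; acceptance runs more)
  wins <- 0
  for (r in 1:20) {
    set.seed(900 + r)
    survCov <- list(N_obj = matrix(rpois(100 * 4, 4), 100, 4),
                    Soil = matrix(runif(100 * 4), 100, 4))
    tr <- truthParams(betaPsiTrue = qlogis(0.5),
                      alphaPTrue = c(qlogis(0.4), 1.2, 0),
                      missingFraction = 0)
    d <- simulateDetectionHistories(NULL, survCov, tr, 100, 4,
                                    seed = 900 + r)
    sel <- twoStageSelection(d,
      detectionCandidates = list(character(0), "N_obj", "Soil"),
      occupancyCandidates = list(character(0)), nStarts = 2, seed = r)
    if (identical(sel$bestDetection, "N_obj")) wins <- wins + 1
  }
  expect_gte(wins, 18)

  ## one candidate per stage is trivially selected; table row counts match
  d1 <- simulateDetectionHistories(NULL, NULL, truthParams(), 30, 5,
                                   seed = 3)
  one <- twoStageSelection(d1, list("dummy"[0]), list(character(0)))
  expect_identical(one$bestDetection, character(0))
  expect_equal(nrow(one$stage2Table), 1)

  siteCov <- data.frame(a = rnorm(30), b = rnorm(30))
  d2 <- simulateDetectionHistories(siteCov, NULL,
    truthParams(betaPsiTrue = c(0, 0, 0)), 30, 5, seed = 4)
  multi <- twoStageSelection(d2, list(character(0)),
                             list(character(0), "a", "b", c("a", "b")))
  expect_equal(nrow(multi$stage2Table), 4)

  ## the one-or-two-covariate structure is enforced
  expect_error(twoStageSelection(d2, list(character(0)),
                                 list(c("a", "b", "a"))), "2-covariate")
})

test_that("the bootstrap GOF statistic and p-value behave sensibly", {
  ## hand-checkable statistic on a tiny complete design
  y <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  d <- detectionDataFromY(y)
  f <- fitOccupancy(d, nStarts = 3)
  psi <- plogis(f@betaPsi); p <- plogis(f@alphaP)
  hist <- expand.grid(o1 = 0:1, o2 = 0:1)
  probs <- apply(hist, 1, function(h)
    psi * prod(ifelse(h == 1, p, 1 - p)) + (1 - psi) * all(h == 0))
  E <- 3 * probs
  keys <- apply(hist, 1, paste, collapse = "")
  O <- as.numeric(table(factor(apply(y, 1, paste, collapse = ""),
                               levels = keys)))
  tExp <- sum((O[O > 0] - E[O > 0])^2 / E[O > 0]) + sum(E[O == 0])
  expect_equal(occuRange:::mbChiSq(f, d), tExp, tolerance = 1e-8)

  ## p-value is a proper proportion, and well-specified data are not
  ## rejected wildly (single run; calibration is in the acceptance suite)
  tr <- truthParams(betaPsiTrue = qlogis(0.5), alphaPTrue = qlogis(0.5),
                    missingFraction = 5 / 150)
  dd <- simulateDetectionHistories(NULL, NULL, tr, 30, 5, seed = 8)
  ff <- fitOccupancy(dd)
  g <- parametricBootstrapGOF(ff, dd, nSim = 100, seed = 9)
  expect_gte(g$pval, 1 / 101)
  expect_lte(g$pval, 1)
  expect_length(g$simulated, 100)
})

test_that("prediction curves back-transform with valid delta-method limits", {
  siteCov <- data.frame(Veg_H = runif(150, 0.5, 5))
  tr <- truthParams(betaPsiTrue = c(0.5, -1.1), alphaPTrue = qlogis(0.6),
                    missingFraction = 0)
  d <- simulateDetectionHistories(siteCov, NULL, tr, 150, 5, seed = 13)
  f <- fitOccupancy(d, psiCovariates = "Veg_H")
  cur <- predictCurves(f, "Veg_H", grid = seq(0.5, 5, 0.5))
  ## declining occupancy with vegetation height: psi(4 m) < psi(1 m)
  expect_lt(cur$estimate[cur$value == 4], cur$estimate[cur$value == 1])
  expect_true(all(cur$lower > 0 & cur$upper < 1))
  expect_true(all(cur$lower <= cur$estimate & cur$estimate <= cur$upper))
  ## monotone when the slope is single-signed
  expect_true(all(diff(cur$estimate) < 0))

  ## the threshold inverse lands back on the curve
  vegAt <- psiThresholdCovariate(f, "Veg_H", 0.5)
  back <- predictCurves(f, "Veg_H", vegAt)
  expect_equal(back$estimate, 0.5, tolerance = 1e-9)

  ## zero slope -> flat curve at the intercept's inverse logit
  f0 <- f
  f0@betaPsi[["Veg_H"]] <- 0
  flat <- predictCurves(f0, "Veg_H", c(1, 2, 3))
  expect_true(all(flat$estimate == plogis(f0@betaPsi[["(Intercept)"]])))
})

test_that("naive occupancy counts detected sites among conducted surveys", {
  y <- matrix(0L, 30, 5)
  y[seq_len(7), 1] <- 1L
  d <- detectionDataFromY(y)
  expect_equal(naiveOccupancy(d), 7 / 30)
  expect_equal(round(100 * naiveOccupancy(d)), 23)
  expect_equal(naiveOccupancy(detectionDataFromY(matrix(0L, 5, 3))), 0)

  ## psi = 1 generator: naive occupancy approaches 1 as occasions grow
  tr <- truthParams(betaPsiTrue = 20, alphaPTrue = qlogis(0.5),
                    missingFraction = 0)
  naive <- vapply(c(1, 3, 8), function(J)
    naiveOccupancy(simulateDetectionHistories(NULL, NULL, tr, 400, J,
                                              seed = J)), 0)
  expect_true(all(diff(naive) > 0))
  expect_gt(naive[3], 0.95)
})
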