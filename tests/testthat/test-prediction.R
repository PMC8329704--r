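test_that("feature assembly z-scores columns and concatenates modalities", {
  set.seed(60)
  fc <- synthFeatureCohort(n = 20, featuresPerModality = 2, seed = 3)
  asm <- assembleFeatures(fc$features, fc$li)
  expect_named(asm$sets, c("eeg", "smri", "alff", "fc", "multimodal"))
  for (s in asm$sets) {
    expect_lt(max(abs(colMeans(s@x))), 1e-10)
    expect_equal(unname(apply(s@x, 2, sd)), rep(1, ncol(s@x)))
  }
  expect_equal(ncol(asm$sets$multimodal@x),
               sum(vapply(asm$sets[1:4], function(s) ncol(s@x), integer(1))))
  expect_equal(mean(asm$li), 0, tolerance = 1e-10)
  expect_equal(sd(asm$li), 1)
  # a single selected cell gives a one-column set
  one <- assembleFeatures(list(eeg = fc$features$eeg[, 1, drop = FALSE]),
                          fc$li)
  expect_equal(ncol(one$sets$eeg@x), 1L)
  expect_false("multimodal" %in% names(one$sets))
})

test_that("degenerate modalities fall back to a flagged single column", {
  set.seed(61)
  li <- rnorm(15)
  empty <- matrix(numeric(0), 15, 0)
  fb <- matrix(rnorm(15), ncol = 1, dimnames = list(NULL, "best"))
  asm <- assembleFeatures(list(eeg = empty, fc = matrix(rnorm(30), 15)),
                          li, fallback = list(eeg = fb))
  expect_true(asm$sets$eeg@degenerate)
  expect_false(asm$sets$fc@degenerate)
  expect_equal(asm$sets$eeg@provenance, "best")
})

test_that("LOOCV with a linear model matches a hand-rolled fold loop", {
  set.seed(62)
  n <- 15
  x <- matrix(rnorm(n), ncol = 1)
  y <- 1.5 * drop(x) + 0.3 + 0.2 * rnorm(n)
  mine <- loocvPredict(x, y, "linear")
  byHand <- vapply(seq_len(n), function(i) {
    fit <- lm(y ~ x, data = data.frame(y = y[-i], x = x[-i, 1]))
    predict(fit, data.frame(x = x[i, 1]))
  }, numeric(1))
  expect_equal(mine, unname(byHand), tolerance = 1e-10)
})

test_that("noiseless linear relations are recovered perfectly by LOOCV", {
  set.seed(63)
  x <- matrix(rnorm(20), ncol = 1)
  y <- drop(2 * x - 1)
  for (model in c("linear", "ardr")) {
    pr <- loocvPredict(x, y, model)
    ev <- evaluatePredictions(pr, y)
    expect_lt(ev$mae, 1e-6)
    expect_gt(ev$r, 0.999999)
  }
  ev <- evaluatePredictions(loocvPredict(x, y, "svr_linear"), y)
  expect_lt(ev$mae, 0.12)       # epsilon-insensitive tube
  expect_gt(ev$r, 0.99)
})

test_that("no leakage: the held-out value never influences its own prediction", {
  set.seed(64)
  n <- 12
  x <- matrix(rnorm(n * 3), n)
  y <- rnorm(n)
  for (model in c("linear", "svr_linear", "ardr", "rfr")) {
    p1 <- loocvPredict(x, y, model, seed = 5)
    for (i in c(1, n %/% 2)) {
      yc <- y; yc[i] <- yc[i] + 1000
      p2 <- loocvPredict(x, yc, model, seed = 5)
      expect_equal(p2[i], p1[i], tolerance = 1e-8)
    }
  }
})

test_that("random-forest LOOCV is reproducible under a fixed seed", {
  set.seed(65)
  x <- matrix(rnorm(30), ncol = 2)
  y <- rnorm(15)
  expect_identical(loocvPredict(x, y, "rfr", seed = 11),
                   loocvPredict(x, y, "rfr", seed = 11))
  expect_error(loocvPredict(x, y, "nonsense"))
  expect_error(loocvPredict(x[1:2, ], y[1:2], "linear"), "at least 3")
})

test_that("evaluation metrics follow their definitions", {
  y <- c(-1, 0, 2, 4)
  expect_equal(evaluatePredictions(y, y), list(mae = 0, r = 1))
  ev <- evaluatePredictions(y + 0.7, y)
  expect_equal(ev$mae, 0.7)
  expect_equal(ev$r, 1)
  expect_equal(evaluatePredictions(-y, y)$r, -1)
})

test_that("Steiger's dependent-correlation z behaves as expected", {
  out <- compareDependentCorrelations(0.7, 0.7, 0.4, 27)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
  expect_gt(compareDependentCorrelations(0.8, 0.3, 0.5, 27)$z, 0)
  expect_lt(compareDependentCorrelations(0.3, 0.8, 0.5, 27)$z, 0)
})

test_that("Steiger p agrees with a resampling-based comparison", {
  set.seed(66)
  n <- 60
  base <- rnorm(n)
  y <- base + 0.6 * rnorm(n)
  x1 <- base + 0.6 * rnorm(n)      # stronger predictor
  x2 <- base + 2.0 * rnorm(n)      # weaker predictor
  r1 <- cor(y, x1); r2 <- cor(y, x2); r12 <- cor(x1, x2)
  ps <- compareDependentCorrelations(r1, r2, r12, n)$p
  # permutation null: swap x1/x2 labels within participants
  dObs <- abs(atanh(r1) - atanh(r2))
  dPerm <- replicate(999, {
    sw <- runif(n) < 0.5
    a <- ifelse(sw, x2, x1); b <- ifelse(sw, x1, x2)
    abs(atanh(cor(y, a)) - atanh(cor(y, b)))
  })
  pPerm <- (1 + sum(dPerm >= dObs)) / 1000
  expect_lt(abs(ps - pPerm), 0.05)
})

test_that("the report compares every single modality against multimodal", {
  fcoh <- synthFeatureCohort(n = 24, seed = 8)
  asm <- assembleFeatures(fcoh$features, fcoh$li)
  rep <- predictLearning(asm, models = "svr_linear", seed = 2)
  sc <- predictionScores(rep)
  expect_setequal(sc$featureSet, c("eeg", "smri", "alff", "fc", "multimodal"))
  expect_true(all(sc$mae >= 0))
  expect_true(all(abs(sc$r) <= 1, na.rm = TRUE))
  expect_equal(nrow(rep@comparisons), 4L)
  expect_equal(rep@comparisons$z,
               with(rep@comparisons, ifelse(rMulti > rSingle, abs(z), -abs(z))))
  # a single-column set is fitted with plain linear regression instead of SVR
  one <- assembleFeatures(list(eeg = fcoh$features$eeg[, 1, drop = FALSE],
                               fc = fcoh$features$fc), fcoh$li)
  rep2 <- predictLearning(one, models = "svr_linear", seed = 2)
  sc2 <- predictionScores(rep2)
  expect_equal(sc2$modelUsed[sc2$featureSet == "eeg"], "linear")
})
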