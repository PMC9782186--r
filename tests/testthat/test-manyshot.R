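test_that("the l2 grid is geometric with the stated endpoints", {
  g <- l2Grid()
  expect_length(g, 45)
  expect_equal(g[1], 1e-6)
  expect_equal(g[45], 1e5)
  ratios <- g[-1] / g[-45]
  expect_equal(ratios, rep((1e5 / 1e-6)^(1 / 44), 44), tolerance = 1e-12)
})

probeSplits <- function(X, y, seed = 1) {
  withr::with_seed(seed, {
    n <- length(y)
    idx <- sample(n)
    nTr <- round(0.7 * n); nVal <- round(0.15 * n)
    list(
      trX = X[idx[1:nTr], ], trY = y[idx[1:nTr]],
      vaX = X[idx[(nTr + 1):(nTr + nVal)], ], vaY = y[idx[(nTr + 1):(nTr + nVal)]],
      teX = X[idx[(nTr + nVal + 1):n], ], teY = y[idx[(nTr + nVal + 1):n]]
    )
  })
}

test_that("linearly separable Gaussian features give near-perfect probe accuracy", {
  sep <- makeSeparatedFeatures(nPerClass = 60, K = 2, d = 8,
                               separation = 20, seed = 4)
  s <- probeSplits(sep$features, sep$labels)
  pr <- fitLinearProbe(s$trX, s$trY, s$vaX, s$vaY, s$teX, s$teY)
  expect_gte(pr@testAccuracy, 0.95)
  expect_true(pr@chosenLambda %in% l2Grid())
})

test_that("label-independent features give chance-level probe accuracy", {
  withr::with_seed(8, {
    X <- matrix(rnorm(400 * 6), 400)
    y <- rep(0:1, each = 200)
  })
  s <- probeSplits(X, y, seed = 2)
  pr <- fitLinearProbe(s$trX, s$trY, s$vaX, s$vaY, s$teX, s$teY)
  nTest <- length(s$teY)
  expect_lt(abs(pr@testAccuracy - 0.5), 3 * sqrt(0.25 / nTest))
})

test_that("duplicating every training point leaves the decision function unchanged", {
  sep <- makeSeparatedFeatures(nPerClass = 30, K = 2, d = 4,
                               separation = 3, seed = 6)
  s <- probeSplits(sep$features, sep$labels)
  grid <- l2Grid()[c(10, 25, 40)]
  p1 <- fitLinearProbe(s$trX, s$trY, s$vaX, s$vaY, s$teX, s$teY,
                       lambdaGrid = grid)
  p2 <- fitLinearProbe(rbind(s$trX, s$trX), c(s$trY, s$trY),
                       s$vaX, s$vaY, s$teX, s$teY, lambdaGrid = grid)
  # per-sample-normalized loss: duplication leaves validation accuracies and
  # hence predictions unchanged at every lambda
  expect_equal(p1@valAccuracy, p2@valAccuracy)
  expect_equal(p1@testAccuracy, p2@testAccuracy)
})

test_that("probe accuracy is invariant to feature column permutation", {
  sep <- makeSeparatedFeatures(nPerClass = 40, K = 3, d = 6,
                               separation = 4, seed = 9)
  s <- probeSplits(sep$features, sep$labels)
  perm <- c(4, 1, 6, 2, 5, 3)
  p1 <- fitLinearProbe(s$trX, s$trY, s$vaX, s$vaY, s$teX, s$teY)
  p2 <- fitLinearProbe(s$trX[, perm], s$trY, s$vaX[, perm], s$vaY,
                       s$teX[, perm], s$teY)
  expect_equal(p1@testAccuracy, p2@testAccuracy)
  expect_equal(p1@chosenLambda, p2@chosenLambda)
  # weights permute with the columns (intercept column excluded); solver
  # tolerance limits the agreement
  expect_equal(unname(p1@weights[, -1][, perm]), unname(p2@weights[, -1]),
               tolerance = 1e-3)
})

test_that("strong regularization shrinks the weight norms", {
  sep <- makeSeparatedFeatures(nPerClass = 40, K = 2, d = 5,
                               separation = 5, seed = 10)
  s <- probeSplits(sep$features, sep$labels)
  pLow <- fitLinearProbe(s$trX, s$trY, s$vaX, s$vaY, s$teX, s$teY,
                         lambdaGrid = c(1e-6, 1e-6 * 1.0001))
  pHigh <- fitLinearProbe(s$trX, s$trY, s$vaX, s$vaY, s$teX, s$teY,
                          lambdaGrid = c(1e5, 1e5 * 1.0001))
  normLow <- sum(pLow@weights[, -1]^2)
  normHigh <- sum(pHigh@weights[, -1]^2)
  expect_lte(normHigh, normLow)
})

test_that("single-class training data is rejected", {
  X <- matrix(rnorm(40), 10)
  expect_error(fitLinearProbe(X, rep(1, 10), X, rep(1, 10), X, rep(1, 10)),
               "single class")
})

# --- finetuning protocol ----------------------------------------------------

tinySplits <- function(spec, nPerClass = 40) {
  ds <- generateDataset(spec, nPerClass)
  n <- nPerClass
  tr <- c(1:(0.7 * n), n + 1:(0.7 * n))
  va <- c((0.7 * n + 1):(0.85 * n), n + (0.7 * n + 1):(0.85 * n))
  te <- c((0.85 * n + 1):n, n + (0.85 * n + 1):n)
  list(train = ds[tr], val = ds[va], test = ds[te])
}

test_that("early stopping halts after patience consecutive non-improving checks", {
  spec <- smallSpec(imageSize = 12L, signalRegion = c(1L, 1L, 12L, 12L))
  sp <- tinySplits(spec, 20)
  cnn <- makeToyExtractor("tiny_cnn", featureDim = 2, seed = 1,
                          inputSize = c(12, 12))
  cfg <- finetuneConfig(maxSteps = 5000, evalEvery = 200,
                        earlyStopPatience = 3, batchSize = 8)
  # strictly decreasing validation metric: first check counts as the best,
  # the next three fail -> stop at step 800
  ft <- finetune(cnn, sp$train, sp$val, sp$test, cfg, seed = 1,
                 valAccuracyFn = function(step) 1 - step / 10000)
  expect_identical(ft$stoppedAt, 800L)
  expect_equal(ft$log$step, c(200L, 400L, 600L, 800L))

  # ever-improving metric: runs to maxSteps
  cfg2 <- finetuneConfig(maxSteps = 600, evalEvery = 200,
                         earlyStopPatience = 3, batchSize = 8)
  ft2 <- finetune(cnn, sp$train, sp$val, sp$test, cfg2, seed = 1,
                  valAccuracyFn = function(step) step / 10000)
  expect_identical(ft2$stoppedAt, 600L)
  expect_gte(nrow(ft2$log), 3)
})

test_that("maxSteps = 0 evaluates the initial model with an empty log", {
  spec <- smallSpec(imageSize = 12L, signalRegion = c(1L, 1L, 12L, 12L))
  sp <- tinySplits(spec, 20)
  cnn <- makeToyExtractor("tiny_cnn", featureDim = 2, seed = 1,
                          inputSize = c(12, 12))
  ft <- finetune(cnn, sp$train, sp$val, sp$test,
                 finetuneConfig(maxSteps = 0), seed = 1)
  expect_identical(nrow(ft$log), 0L)
  expect_identical(ft$extractor@params, cnn@params)
  expect_true(ft$testAccuracy >= 0 && ft$testAccuracy <= 1)
})

test_that("finetuning is refused for non-trainable extractors", {
  ex <- makeToyExtractor("random_projection", 4, seed = 1, inputSize = c(8, 8))
  ds <- generateDataset(smallSpec(imageSize = 8L,
                                  signalRegion = c(1L, 1L, 8L, 8L)), 4)
  expect_error(finetune(ex, ds, ds, ds), "trainable")
})

test_that("finetuning beats the untrained probe on noisy texture classes", {
  # full-image orientation texture buried in heavy pixel noise: untrained
  # pooled-conv features are informative but imperfect; training the filters
  # recovers the texture orientation
  spec <- syntheticSpec(imageSize = 16L, nClasses = 2,
                        signalRegion = c(1L, 1L, 16L, 16L),
                        signalAmplitude = 0.3, noiseSigma = 0.3, seed = 21L)
  ds <- generateDataset(spec, 50)
  tr <- c(1:35, 51:85); va <- c(36:42, 86:92); te <- c(43:50, 93:100)
  cnn <- makeToyExtractor("tiny_cnn", featureDim = 2, seed = 1,
                          inputSize = c(16, 16))
  eTr <- embedDataset(cnn, ds[tr])
  eVa <- embedDataset(cnn, ds[va])
  eTe <- embedDataset(cnn, ds[te])
  untrained <- fitLinearProbe(eTr$features, eTr$labels, eVa$features,
                              eVa$labels, eTe$features, eTe$labels)
  cfg <- finetuneConfig(maxSteps = 800, evalEvery = 100, batchSize = 16,
                        augment = FALSE)
  ft <- finetune(cnn, ds[tr], ds[va], ds[te], cfg, seed = 2)
  expect_gt(ft$testAccuracy, untrained@testAccuracy)
  expect_lte(ft$stoppedAt, 800L)
})
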