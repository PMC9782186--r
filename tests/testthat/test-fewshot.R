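test_that("episodes have the stated shape and sampling semantics", {
  feats <- matrix(rnorm(200 * 8), 200)
  labs <- rep(0:3, each = 50)

  set.seed(1)
  ep <- sampleEpisode(feats, labs, K = 2, N = 20, NQ = 15)
  expect_length(ep@supportLabels, 40)
  expect_length(ep@queryLabels, 30)
  expect_length(ep@classIds, 2)
  # support and query are disjoint row sets
  expect_equal(nrow(unique(rbind(ep@supportFeatures, ep@queryFeatures))), 70)

  # exhaustive case: dataset of exactly K classes with exactly N + NQ images
  featsX <- matrix(rnorm(70 * 4), 70)
  labsX <- rep(0:1, each = 35)
  epX <- sampleEpisode(featsX, labsX, K = 2, N = 20, NQ = 15)
  used <- rbind(epX@supportFeatures, epX@queryFeatures)
  expect_equal(nrow(unique(used)), 70)

  # identical RNG state twice gives identical episodes
  set.seed(42); e1 <- sampleEpisode(feats, labs, 2, 5, 5)
  set.seed(42); e2 <- sampleEpisode(feats, labs, 2, 5, 5)
  expect_identical(e1@supportFeatures, e2@supportFeatures)
  expect_identical(e1@queryFeatures, e2@queryFeatures)

  expect_error(sampleEpisode(feats, labs, K = 5, N = 5, NQ = 5), "classes")
  expect_error(sampleEpisode(feats, labs, K = 2, N = 40, NQ = 15), "class")
})

test_that("prototypes are support centroids", {
  # identical support features collapse to that vector
  f <- matrix(rep(c(1, 2, 3), each = 4), 4)
  ep <- new("Episode", supportFeatures = f, supportLabels = rep(0L, 4),
            queryFeatures = f, queryLabels = rep(0L, 4), classIds = 0L)
  expect_equal(computePrototypes(ep)@prototypes[1, ], c(1, 2, 3))

  # midpoint of two points
  ep2 <- new("Episode",
             supportFeatures = rbind(c(0, 0), c(2, 2)),
             supportLabels = c(5L, 5L),
             queryFeatures = rbind(c(0, 0)), queryLabels = 5L, classIds = 5L)
  expect_equal(computePrototypes(ep2)@prototypes[1, ], c(1, 1))

  # random support: prototypes equal independently recomputed column means
  set.seed(3)
  X <- matrix(rnorm(20 * 7), 20)
  y <- rep(c(1L, 2L), each = 10)
  ep3 <- new("Episode", supportFeatures = X, supportLabels = y,
             queryFeatures = X[1:2, ], queryLabels = y[1:2], classIds = c(1L, 2L))
  pr <- computePrototypes(ep3)
  for (k in 1:2) {
    manual <- colSums(X[y == k, ]) / 10
    expect_equal(pr@prototypes[pr@classIds == k, ], manual, tolerance = 1e-14)
  }
})

test_that("queries go to the nearest prototype with low-id tie-breaking", {
  protos <- new("PrototypeSet", prototypes = rbind(c(0, 0), c(2, 0)),
                classIds = c(3L, 7L))
  expect_equal(classifyQueries(protos, rbind(c(0, 0))), 3L)
  expect_equal(classifyQueries(protos, rbind(c(2, 0.1))), 7L)
  # exactly equidistant: lower class id wins
  expect_equal(classifyQueries(protos, rbind(c(1, 5))), 3L)
  expect_error(classifyQueries(protos, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("pipeline predictions match the brute-force nearest-centroid oracle", {
  set.seed(7)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    d <- sample(2:32, 1)
    N <- sample(2:20, 1)
    feats <- matrix(rnorm(K * (N + 10) * d), ncol = d)
    labs <- rep(seq_len(K) - 1L, each = N + 10)
    ep <- sampleEpisode(feats, labs, K, N, NQ = 10)
    pred <- classifyQueries(computePrototypes(ep), ep@queryFeatures)
    oracle <- bruteNearestCentroid(ep@supportFeatures, ep@supportLabels,
                                   ep@queryFeatures)
    expect_identical(pred, as.integer(oracle))
  }
})

test_that("episodic accuracy is invariant under orthogonal transform plus translation", {
  set.seed(11)
  feats <- matrix(rnorm(120 * 6), 120)
  labs <- rep(0:1, each = 60)
  d <- 6
  Q <- qr.Q(qr(matrix(rnorm(d * d), d))) # random orthogonal matrix
  shift <- rnorm(d)
  featsT <- feats %*% Q + matrix(shift, nrow(feats), d, byrow = TRUE)
  r1 <- evaluateFewshot(feats, labs, K = 2, N = 10, NQ = 10,
                        nEpisodes = 40, seed = 5)
  r2 <- evaluateFewshot(featsT, labs, K = 2, N = 10, NQ = 10,
                        nEpisodes = 40, seed = 5)
  expect_equal(r1@perEpisodeAccuracy, r2@perEpisodeAccuracy, tolerance = 1e-9)
})

test_that("label-shuffled features sit at chance level", {
  set.seed(13)
  feats <- matrix(rnorm(300 * 16), 300)
  labs <- rep(0:2, each = 100)
  r <- evaluateFewshot(feats, labs, K = 3, N = 10, NQ = 10,
                       nEpisodes = 200, seed = 3)
  expect_lt(abs(r@meanAccuracy - 1 / 3), 3 * r@ci95Halfwidth)
  expect_equal(r@meanAccuracy, mean(r@perEpisodeAccuracy))
})

test_that("well-separated clusters give perfect episodic accuracy", {
  sep <- makeSeparatedFeatures(nPerClass = 40, K = 5, d = 16,
                               separation = 100, seed = 2)
  r <- evaluateFewshot(sep$features, sep$labels, K = 5, N = 20, NQ = 15,
                       nEpisodes = 50, seed = 1)
  expect_equal(r@meanAccuracy, 1.0)
})

test_that("episodic evaluation is reproducible and order-independent in the seed", {
  set.seed(17)
  feats <- matrix(rnorm(150 * 4), 150)
  labs <- rep(0:2, each = 50)
  r1 <- evaluateFewshot(feats, labs, 2, 10, 10, nEpisodes = 30, seed = 9)
  r2 <- evaluateFewshot(feats, labs, 2, 10, 10, nEpisodes = 30, seed = 9)
  expect_identical(r1@perEpisodeAccuracy, r2@perEpisodeAccuracy)
  # first 10 episodes of a longer run equal a 10-episode run
  r3 <- evaluateFewshot(feats, labs, 2, 10, 10, nEpisodes = 10, seed = 9)
  expect_identical(r3@perEpisodeAccuracy, r1@perEpisodeAccuracy[1:10])
})
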