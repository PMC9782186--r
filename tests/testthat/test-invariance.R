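test_that("moment estimation uses the whole dataset when small and caps at 1000", {
  ds <- generateDataset(smallSpec(), 25) # 50 images
  ex <- makeToyExtractor("random_projection", 4, seed = 1, inputSize = c(32, 32))
  mom <- estimateMoments(ex, ds, seed = 1)
  expect_identical(mom@nImages, 50L)
  # duplicated dataset, sample covers everything: identical mean feature
  dup <- ds[rep(seq_len(50), 2)]
  momDup <- estimateMoments(ex, dup, seed = 1, maxImages = 2000L)
  expect_equal(mom@meanFeature, momDup@meanFeature, tolerance = 1e-12)

  # L reproduces the precision matrix
  prec <- mom@L %*% t(mom@L)
  expect_equal(prec, solve(mom@sigma), tolerance = 1e-8)
})

test_that("i.i.d. standard-normal features give near-identity moments", {
  withr::with_seed(21, {
    feats <- matrix(rnorm(1000 * 4), 1000)
  })
  idExtractor <- new("FeatureExtractor", id = "passthrough", featureDim = 4L,
                     preprocess = preprocessSpec(resizeSide = NA, cropSize = NA,
                                                 normalization = "none",
                                                 stackChannels = FALSE),
                     embedFun = function(px) as.numeric(px),
                     linearMap = diag(4), inputDim = c(1L, 4L, 1L),
                     trainable = FALSE)
  imgs <- lapply(seq_len(1000), function(i) {
    m <- matrix(pmin(pmax((feats[i, ] + 5) / 10, 0), 1), 1) # into [0,1]
    m
  })
  ds <- new("LabeledImageSet", images = imgs,
            label = rep(0L, 1000), groupId = rep(NA_integer_, 1000),
            viewId = rep(NA_integer_, 1000), nClasses = 1L)
  mom <- estimateMoments(idExtractor, ds, seed = 1)
  # pixel scale is (f + 5) / 10, so covariance is I / 100 up to sampling error
  expect_lt(max(abs(mom@sigma - diag(4) / 100)), 0.0015)
  expect_equal(mom@nImages, 1000L)
})

test_that("whitening matches the identity and Mahalanobis closed forms", {
  mom <- new("InvarianceMoments", meanFeature = c(1, 2, 3),
             sigma = diag(3), L = diag(3), nImages = 10L, ridge = 0)
  expect_equal(whitenFeature(c(1, 2, 3), mom), c(0, 0, 0))
  f <- c(0.5, -1, 2)
  expect_equal(whitenFeature(f, mom), c(1, 2, 3) - f)

  # arbitrary SPD covariance: |z|^2 equals the Mahalanobis quadratic form
  withr::with_seed(4, {
    A <- matrix(rnorm(25), 5)
    sigma <- crossprod(A) + diag(5) * 0.1
    fbar <- rnorm(5)
    feat <- rnorm(5)
  })
  sinv <- solve(sigma)
  L <- t(chol(sinv))
  momS <- new("InvarianceMoments", meanFeature = fbar, sigma = sigma,
              L = L, nImages = 10L, ridge = 0)
  z <- whitenFeature(feat, momS)
  mah <- as.numeric(t(fbar - feat) %*% sinv %*% (fbar - feat))
  expect_equal(sum(z^2), mah, tolerance = 1e-10)
  expect_error(whitenFeature(rnorm(4), momS), "dimension mismatch")
})

test_that("a flip-invariant extractor scores exactly 1 on the flip family", {
  ds <- generateDataset(smallSpec(seed = 3L), 30)
  ex <- makeToyExtractor("flip_invariant", featureDim = 8, seed = 2,
                         inputSize = c(32, 32))
  mom <- estimateMoments(ex, ds, seed = 1)
  r <- invarianceScore(ex, ds, flipFamily(), mom, nEval = 20, seed = 1)
  expect_equal(r@score, 1.0, tolerance = 1e-9)
})

test_that("features reflected through the mean score exactly -1", {
  # dataset containing x and its intensity inversion 1 - x for every object:
  # the sample mean image is exactly 0.5, so for a linear extractor
  # f(1 - x) = 2 fbar - f(x) and the whitened features are antipodal
  base <- generateDataset(smallSpec(seed = 5L, noiseSigma = 0.02), 20)
  imgs <- c(images(base), lapply(images(base), function(x) 1 - x))
  n <- length(imgs)
  ds <- new("LabeledImageSet", images = imgs, label = rep(0L, n),
            groupId = rep(NA_integer_, n), viewId = rep(NA_integer_, n),
            nClasses = 1L)
  ex <- makeToyExtractor("random_projection", 8, seed = 7,
                         inputSize = c(32, 32))
  mom <- estimateMoments(ex, ds, seed = 1)
  inversion <- transformFamily("inversion", list(TRUE),
                               function(x, theta) 1 - x)
  r <- invarianceScore(ex, ds, inversion, mom, nEval = 40, seed = 2)
  expect_equal(r@score, -1.0, tolerance = 1e-9)
})

test_that("all invariance scores lie in [-1, 1] across families and extractors", {
  ds <- generateDataset(smallSpec(seed = 9L, channels = 3L), 20)
  for (kind in c("random_projection", "flip_invariant")) {
    ex <- makeToyExtractor(kind, 6, seed = 1, inputSize = c(32, 32, 3))
    mom <- estimateMoments(ex, ds, seed = 1)
    for (fam in list(flipFamily(), rotationFamily(), hueFamily())) {
      r <- invarianceScore(ex, ds, fam, mom, nEval = 10, seed = 1)
      expect_lte(abs(r@score), 1 + 1e-9)
    }
  }
})

test_that("a generic extractor is less rotation-invariant than a flip-invariant one is to flips", {
  ds <- generateDataset(smallSpec(seed = 13L), 30)
  exF <- makeToyExtractor("flip_invariant", 8, seed = 3, inputSize = c(32, 32))
  exG <- makeToyExtractor("random_projection", 8, seed = 3, inputSize = c(32, 32))
  momF <- estimateMoments(exF, ds, seed = 1)
  momG <- estimateMoments(exG, ds, seed = 1)
  flipScore <- invarianceScore(exF, ds, flipFamily(), momF, nEval = 25, seed = 4)
  rotScore <- invarianceScore(exG, ds, rotationFamily(), momG, nEval = 25, seed = 4)
  expect_lt(rotScore@score, flipScore@score)
})

test_that("hue on stacked-grayscale images is flagged as a no-op", {
  ds <- generateDataset(smallSpec(seed = 2L, channels = 3L), 10)
  ex <- makeToyExtractor("random_projection", 4, seed = 1,
                         inputSize = c(32, 32, 3))
  mom <- estimateMoments(ex, ds, seed = 1)
  r <- invarianceScore(ex, ds, hueFamily(), mom, nEval = 5, seed = 1)
  expect_match(r@notes, "no-op")
  expect_equal(r@score, 1.0, tolerance = 1e-6)
})

test_that("invariance scores are invariant to linear reparameterization of features", {
  # re-expressing features through any invertible linear map, with moments
  # re-estimated, must leave whitened cosines unchanged (d <= 8)
  ds <- generateDataset(smallSpec(seed = 17L), 25)
  ex <- makeToyExtractor("random_projection", 5, seed = 5, inputSize = c(32, 32))
  withr::with_seed(6, A <- matrix(rnorm(25), 5) + diag(5) * 2)
  exT <- new("FeatureExtractor", id = "reparam", featureDim = 5L,
             preprocess = ex@preprocess,
             embedFun = function(px) as.numeric(A %*% ex@embedFun(px)),
             linearMap = A %*% ex@linearMap, inputDim = ex@inputDim,
             trainable = FALSE)
  mom <- estimateMoments(ex, ds, seed = 1)
  momT <- estimateMoments(exT, ds, seed = 1)
  r <- invarianceScore(ex, ds, rotationFamily(), mom, nEval = 15, seed = 2)
  rT <- invarianceScore(exT, ds, rotationFamily(), momT, nEval = 15, seed = 2)
  expect_equal(r@score, rT@score, tolerance = 1e-6)
})

test_that("multi-view invariance: identical views score 1, shuffled pairs near 0", {
  specZero <- smallSpec(multiviewShift = 0L, seed = 19L)
  mvZero <- suppressWarnings(generateMultiviewPairs(specZero, 60))
  ex <- makeToyExtractor("random_projection", 32, seed = 2,
                         inputSize = c(32, 32))
  momZ <- estimateMoments(ex, mvZero, seed = 1)
  rZ <- multiviewInvariance(ex, mvZero, momZ, nEval = 50, seed = 1)
  expect_equal(rZ@score, 1.0, tolerance = 1e-9)

  # null pairing: re-pair unrelated objects; |score| < 0.2 at d = 32
  n <- length(mvZero)
  v1 <- which(viewIds(mvZero) == 1L)
  shuffled <- mvZero
  withr::with_seed(3, newGid <- sample(groupIds(mvZero)[v1]))
  shuffled@groupId[v1] <- newGid
  momS <- estimateMoments(ex, shuffled, seed = 1)
  rS <- multiviewInvariance(ex, shuffled, momS, nEval = 50, seed = 1)
  expect_lt(abs(rS@score), 0.2)

  # reproducible under a fixed seed
  rS2 <- multiviewInvariance(ex, shuffled, momS, nEval = 50, seed = 1)
  expect_identical(rS@score, rS2@score)
})

test_that("incomplete view pairs are excluded with a warning", {
  spec <- smallSpec(multiviewShift = 4L, seed = 23L)
  mv <- generateMultiviewPairs(spec, 10)
  broken <- mv[1:19] # drop one view of the last pair
  ex <- makeToyExtractor("random_projection", 4, seed = 1, inputSize = c(32, 32))
  mom <- estimateMoments(ex, mv, seed = 1)
  expect_warning(r <- multiviewInvariance(ex, broken, mom, nEval = 20, seed = 1),
                 "pair")
  expect_identical(r@nEval, 9L)
})
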