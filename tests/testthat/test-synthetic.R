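test_that("invalid specifications are rejected at construction", {
  expect_error(syntheticSpec(nClasses = 1), "nClasses")
  expect_error(syntheticSpec(imageSize = 32, signalRegion = c(20, 20, 20, 20)),
               "inside the image")
  expect_error(syntheticSpec(signalAmplitude = -1), "signalAmplitude")
  expect_error(syntheticSpec(channels = 2), "channels")
  expect_error(generateDataset(smallSpec(), nPerClass = 0), "nPerClass")
})

test_that("identical spec and seed give byte-identical datasets", {
  d1 <- generateDataset(smallSpec(seed = 7L), 4)
  d2 <- generateDataset(smallSpec(seed = 7L), 4)
  expect_identical(images(d1), images(d2))
  expect_identical(imageLabels(d1), imageLabels(d2))
  d3 <- generateDataset(smallSpec(seed = 8L), 4)
  expect_false(identical(images(d1), images(d3)))
})

test_that("growing a dataset never perturbs existing images", {
  small <- generateDataset(smallSpec(), 3)
  large <- generateDataset(smallSpec(), 6)
  for (k in 0:1) {
    expect_identical(images(small)[imageLabels(small) == k],
                     images(large)[imageLabels(large) == k][1:3])
  }
})

test_that("zero signal amplitude and zero noise make classes pixel-identical", {
  ds <- generateDataset(smallSpec(signalAmplitude = 0, noiseSigma = 0), 3)
  expect_length(images(ds), 6)
  expect_identical(images(ds)[imageLabels(ds) == 0],
                   images(ds)[imageLabels(ds) == 1])
})

test_that("class signal is confined to the signal region", {
  # noise off: class-mean images must agree EXACTLY outside the region
  spec <- smallSpec(noiseSigma = 0)
  ds <- generateDataset(spec, 5)
  m0 <- Reduce(`+`, images(ds)[imageLabels(ds) == 0]) / 5
  m1 <- Reduce(`+`, images(ds)[imageLabels(ds) == 1]) / 5
  r <- spec@signalRegion
  inRegion <- matrix(FALSE, spec@imageSize, spec@imageSize)
  inRegion[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)] <- TRUE
  d <- abs(m0 - m1)
  expect_identical(max(d[!inRegion]), 0)
  expect_gt(mean(d[inRegion]), 0)

  # with noise: mean images over 100 samples per class differ inside the
  # region and only negligibly outside (region-wise mean-image oracle)
  spec2 <- smallSpec(noiseSigma = 0.05)
  ds2 <- generateDataset(spec2, 100)
  mm0 <- Reduce(`+`, images(ds2)[imageLabels(ds2) == 0]) / 100
  mm1 <- Reduce(`+`, images(ds2)[imageLabels(ds2) == 1]) / 100
  dd <- abs(mm0 - mm1)
  expect_gt(mean(dd[inRegion]), 5 * mean(dd[!inRegion]))
  expect_lt(mean(dd[!inRegion]), 0.01)
})

test_that("generated datasets are balanced with labels below nClasses", {
  for (K in c(2L, 3L, 5L)) {
    ds <- generateDataset(smallSpec(nClasses = K), 4)
    expect_equal(as.integer(table(imageLabels(ds))), rep(4L, K))
    expect_true(all(imageLabels(ds) < K))
    rng <- range(unlist(images(ds)))
    expect_gte(rng[1], 0)
    expect_lte(rng[2], 1)
  }
})

test_that("multi-view pairs share a group id and respect the shift bound", {
  spec <- smallSpec(multiviewShift = 8L, imageSize = 48L)
  mv <- generateMultiviewPairs(spec, 50)
  expect_length(mv, 100)
  expect_equal(length(unique(groupIds(mv))), 50)
  expect_true(all(table(groupIds(mv)) == 2))
  expect_setequal(unique(viewIds(mv)), c(1L, 2L))

  # brute-force cross-correlation: paired views align at an offset of at
  # most the configured shift per axis
  for (g in 1:6) {
    rows <- which(groupIds(mv) == g)
    off <- xcorrPeakOffset(images(mv)[[rows[1]]], images(mv)[[rows[2]]],
                           maxShift = 12)
    expect_lte(max(abs(off)), 8)
  }
})

test_that("zero multiview shift warns and yields pixel-identical views", {
  spec <- smallSpec(multiviewShift = 0L)
  expect_warning(mv <- generateMultiviewPairs(spec, 4), "identical")
  for (g in unique(groupIds(mv))) {
    rows <- which(groupIds(mv) == g)
    expect_identical(images(mv)[[rows[1]]], images(mv)[[rows[2]]])
  }
})

test_that("multilabel records have Bernoulli structure and a consistent no-finding flag", {
  expect_error(generateMultilabelRecords(5, character(0), 0.5), "nonempty")
  expect_error(generateMultilabelRecords(5, "a", 1.5), "\\[0, 1\\]")

  rec0 <- generateMultilabelRecords(20, c("a", "b"), c(0, 0), seed = 1)
  expect_true(all(rec0$no_finding))

  rec1 <- generateMultilabelRecords(20, c("a", "b"), c(1, 0), seed = 1)
  expect_true(all(rec1$a == 1) && all(rec1$b == 0) && !any(rec1$no_finding))

  # empirical prevalence within 3 binomial standard deviations of the truth
  n <- 10000
  rec <- generateMultilabelRecords(n, "a", 0.4, seed = 5)
  sd3 <- 3 * sqrt(0.4 * 0.6 / n)
  expect_lt(abs(mean(rec$a) - 0.4), sd3)
  expect_identical(rec$no_finding, rec$a == 0)
})

test_that("image sets round-trip through PNG files and a CSV manifest", {
  spec <- smallSpec(multiviewShift = 4L, imageSize = 24L)
  mv <- generateMultiviewPairs(spec, 3)
  dir <- withr::local_tempdir()
  manifest <- writeImageSet(mv, dir)
  expect_true(file.exists(manifest))
  back <- loadImageSet(manifest, nClasses = nClasses(mv))
  expect_identical(imageLabels(back), imageLabels(mv))
  expect_identical(groupIds(back), groupIds(mv))
  expect_identical(viewIds(back), viewIds(mv))
  # PNG is 8- or 16-bit; intensities survive within quantization error
  err <- max(mapply(function(a, b) max(abs(a - b)), images(back), images(mv)))
  expect_lt(err, 1 / 255)
})
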