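#' Create a synthetic dataset specification
#'
#' The generator plants a class-specific signal mimicking the structure of
#' pathology in medical images: a small local texture perturbation inside a
#' configurable region, on top of a smooth per-object background. Class `k`
#' (0-based) carries a sinusoidal grating oriented at `k * 180 / nClasses`
#' degrees with fixed spatial frequency, of amplitude `signalAmplitude`,
#' confined to `signalRegion`. Gaussian pixel noise of sd `noiseSigma` is
#' added after the signal and intensities are then clipped to `[0, 1]`
#' (clipping after noise breaks exact Gaussianity at the boundaries).
#'
#' Each object instance draws its background, grating phase and noise from
#' RNG streams derived from `(seed, purpose, index)`, so generating more
#' images never perturbs existing ones.
#'
#' @param imageSize pixels per side (default 256).
#' @param nClasses number of classes, >= 2.
#' @param signalRegion integer `(top, left, height, width)`, 1-based, fully
#'   inside the image; default a centered square of side `imageSize / 4`.
#' @param signalAmplitude texture contrast >= 0 (default 0.5).
#' @param noiseSigma pixel noise sd >= 0 (default 0.05).
#' @param channels 1 (grayscale, radiograph-like) or 3.
#' @param multiviewShift maximum per-axis translation in pixels between two
#'   views of the same object (default 0).
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(imageSize = 64, nClasses = 2, seed = 1)
#' ds <- generateDataset(spec, nPerClass = 3)
#' length(ds)
#' @export
syntheticSpec <- function(imageSize = 256L, nClasses = 2L, signalRegion = NULL,
                          signalAmplitude = 0.5, noiseSigma = 0.05,
                          channels = 1L, multiviewShift = 0L, seed = 1L) {
  imageSize <- as.integer(imageSize)
  if (is.null(signalRegion)) {
    side <- max(1L, imageSize %/% 4L)
    off <- (imageSize - side) %/% 2L + 1L
    signalRegion <- c(off, off, side, side)
  }
  new("SyntheticSpec",
    imageSize = imageSize,
    nClasses = as.integer(nClasses),
    signalRegion = as.integer(signalRegion),
    signalAmplitude = as.numeric(signalAmplitude),
    noiseSigma = as.numeric(noiseSigma),
    channels = as.integer(channels),
    multiviewShift = as.integer(multiviewShift),
    seed = as.integer(seed)
  )
}

# Spatial frequency of the class grating, cycles per pixel. Short period
# relative to the image so the signal reads as local texture, not shape.
.gratingFreq <- 0.15

# Render one object instance on a padded canvas. Background and grating
# phase come from objSeed (class-independent, so class-mean images agree
# exactly outside the signal region when noise is off); noise comes from
# noiseSeed. The signal region is placed in final-image coordinates offset
# by `pad` into the canvas.
renderObject <- function(spec, classK, objSeed, noiseSeed, pad = 0L) {
  S <- spec@imageSize
  side <- S + 2L * pad
  coefs <- withSeed(objSeed, {
    list(
      bg = c(stats::runif(1, 0.3, 0.6), stats::runif(5, -0.15, 0.15)),
      phase = stats::runif(1, 0, 2 * pi)
    )
  })
  # normalized coordinates over the canvas
  u <- (seq_len(side) - 1) / max(side - 1, 1)
  X <- matrix(rep(u, each = side), side, side)  # column coordinate
  Y <- matrix(rep(u, times = side), side, side) # row coordinate
  b <- coefs$bg
  img <- b[1] + b[2] * X + b[3] * Y + b[4] * X * Y + b[5] * X^2 + b[6] * Y^2

  if (spec@signalAmplitude > 0) {
    theta <- classK * pi / spec@nClasses
    r <- spec@signalRegion
    rows <- (pad + r[1]):(pad + r[1] + r[3] - 1L)
    cols <- (pad + r[2]):(pad + r[2] + r[4] - 1L)
    RR <- matrix(rep(rows, times = length(cols)), length(rows), length(cols))
    CC <- matrix(rep(cols, each = length(rows)), length(rows), length(cols))
    g <- spec@signalAmplitude *
      sin(2 * pi * .gratingFreq * (CC * cos(theta) + RR * sin(theta)) +
          coefs$phase)
    img[rows, cols] <- img[rows, cols] + g
  }

  if (spec@noiseSigma > 0) {
    img <- img + withSeed(noiseSeed,
                          matrix(stats::rnorm(side * side, 0, spec@noiseSigma),
                                 side, side))
  }
  img
}

.toChannels <- function(img, channels) {
  if (channels == 1L) img else array(rep(img, channels), c(dim(img), channels))
}

#' Generate a balanced synthetic labeled dataset
#'
#' @param spec a [SyntheticSpec-class].
#' @param nPerClass images per class, >= 1.
#' @return a [LabeledImageSet-class] of `nPerClass * nClasses` images ordered
#'   class-major, with balanced 0-based labels.
#' @seealso [syntheticSpec()], [generateMultiviewPairs()]
#' @export
generateDataset <- function(spec, nPerClass) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (!isCount(nPerClass, 1L)) stop("nPerClass must be an integer >= 1")
  K <- spec@nClasses
  imgs <- vector("list", K * nPerClass)
  labels <- integer(K * nPerClass)
  idx <- 1L
  for (k in seq_len(K) - 1L) {
    for (i in seq_len(nPerClass)) {
      img <- renderObject(
        spec, k,
        objSeed = childSeed(spec@seed, paste0("obj:", i)),
        noiseSeed = childSeed(spec@seed, paste0("noise:", k, ":", i))
      )
      imgs[[idx]] <- .toChannels(clip01(img), spec@channels)
      labels[idx] <- k
      idx <- idx + 1L
    }
  }
  new("LabeledImageSet",
    images = imgs, label = labels,
    groupId = rep(NA_integer_, length(imgs)),
    viewId = rep(NA_integer_, length(imgs)),
    nClasses = K
  )
}

#' Generate multi-view image pairs
#'
#' Each pair renders the same object instance (identical background, grating
#' phase and noise field) and extracts two views translated relative to each
#' other by at most `multiviewShift` pixels per axis. With
#' `multiviewShift = 0` the two views are pixel-identical (a warning is
#' emitted).
#'
#' @param spec a [SyntheticSpec-class].
#' @param nPairs number of object instances.
#' @return a [LabeledImageSet-class] of `2 * nPairs` images; views of pair
#'   `p` share `groupId = p` and have `viewId` 1 and 2. Pair classes cycle
#'   through the spec's classes.
#' @export
generateMultiviewPairs <- function(spec, nPairs) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (!isCount(nPairs, 1L)) stop("nPairs must be an integer >= 1")
  s <- spec@multiviewShift
  if (s == 0L && nPairs > 0L)
    warning("multiviewShift is 0: the two views of each pair are identical")
  half <- s %/% 2L
  pad <- half
  S <- spec@imageSize
  imgs <- vector("list", 2L * nPairs)
  labels <- integer(2L * nPairs)
  gid <- integer(2L * nPairs)
  vid <- integer(2L * nPairs)
  for (p in seq_len(nPairs)) {
    k <- (p - 1L) %% spec@nClasses
    canvas <- renderObject(
      spec, k,
      objSeed = childSeed(spec@seed, paste0("mvobj:", p)),
      noiseSeed = childSeed(spec@seed, paste0("mvnoise:", p)),
      pad = pad
    )
    offs <- withSeed(childSeed(spec@seed, paste0("mvshift:", p)),
                     sample.int(2L * half + 1L, 4L, replace = TRUE) - half - 1L)
    for (v in 1:2) {
      dy <- offs[2L * v - 1L]
      dx <- offs[2L * v]
      view <- canvas[(pad + 1L + dy):(pad + S + dy),
                     (pad + 1L + dx):(pad + S + dx)]
      j <- 2L * (p - 1L) + v
      imgs[[j]] <- .toChannels(clip01(view), spec@channels)
      labels[j] <- k
      gid[j] <- p
      vid[j] <- v
    }
  }
  new("LabeledImageSet",
    images = imgs, label = labels, groupId = gid, viewId = vid,
    nClasses = spec@nClasses
  )
}

#' Generate synthetic multi-label records
#'
#' Independent Bernoulli pathology indicators per record, plus a
#' `no_finding` flag that is TRUE exactly when all indicators are FALSE.
#' Useful for exercising label-conversion rules such as many-to-one
#' binarization and single-pathology filtering.
#'
#' @param n number of records.
#' @param pathologyNames nonempty character vector.
#' @param prevalence per-pathology probabilities in `[0, 1]` (recycled to
#'   `length(pathologyNames)`).
#' @param seed RNG seed.
#' @return a data.frame with one 0/1 column per pathology and a logical
#'   `no_finding` column.
#' @export
generateMultilabelRecords <- function(n, pathologyNames, prevalence, seed = 1L) {
  if (length(pathologyNames) == 0L)
    stop("pathologyNames must be nonempty")
  if (!isCount(n, 0L)) stop("n must be a nonnegative integer")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalence probabilities must lie in [0, 1]")
  prevalence <- rep_len(prevalence, length(pathologyNames))
  ind <- withSeed(as.integer(seed), {
    vapply(prevalence, function(p) as.integer(stats::runif(n) < p), integer(n))
  })
  ind <- matrix(ind, nrow = n, ncol = length(pathologyNames),
                dimnames = list(NULL, pathologyNames))
  out <- as.data.frame(ind)
  out$no_finding <- rowSums(ind) == 0
  out
}

#' Write a LabeledImageSet to PNG files with a CSV manifest
#'
#' Writes one PNG per image plus `manifest.csv` with columns
#' `filepath, label, group_id, view_id` — the same manifest format
#' [readImageManifest()] reads back.
#'
#' @param x a [LabeledImageSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
writeImageSet <- function(x, dir) {
  stopifnot(is(x, "LabeledImageSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(x)
  files <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(x@images[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    filepath = files,
    label = x@label,
    group_id = x@groupId,
    view_id = x@viewId
  )
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
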