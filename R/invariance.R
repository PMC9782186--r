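#' Estimate feature-distribution moments for invariance scoring
#'
#' Computes the mean feature and feature covariance from at most 1000 images
#' sampled without replacement (the entire dataset when it has fewer than
#' 1000 images), then the lower-triangular Cholesky-style factor `L` with
#' `L %*% t(L) = solve(sigma)`. If the covariance is not invertible, a ridge
#' `epsilon * I` is added with the smallest epsilon from
#' `{0, 1e-8, 1e-6, 1e-4, ...}` that makes the factorization succeed.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param dataset a [LabeledImageSet-class] (or list of images).
#' @param seed integer seed for the image sample.
#' @param maxImages sample-size cap (default 1000).
#' @return an [InvarianceMoments-class].
#' @export
estimateMoments <- function(extractor, dataset, seed = 1L, maxImages = 1000L) {
  n <- if (is(dataset, "LabeledImageSet")) length(dataset) else length(dataset)
  if (n == 0L) stop("dataset is empty")
  take <- min(n, maxImages)
  idx <- if (take < n) {
    withSeed(childSeed(seed, "moments"), sample.int(n, take))
  } else {
    seq_len(n)
  }
  sub <- if (is(dataset, "LabeledImageSet")) dataset[idx] else dataset[idx]
  feats <- embedDataset(extractor, sub)$features
  d <- ncol(feats)
  fbar <- colMeans(feats)
  sigma0 <- stats::cov(feats)

  for (eps in c(0, 10^seq(-8, 2, by = 2))) {
    sigma <- sigma0 + diag(eps, d)
    fact <- tryCatch({
      sinv <- chol2inv(chol(sigma))
      U <- chol(sinv)
      list(L = t(U), sigma = sigma, eps = eps)
    }, error = function(e) NULL)
    if (!is.null(fact)) {
      return(new("InvarianceMoments",
        meanFeature = fbar,
        sigma = fact$sigma,
        L = fact$L,
        nImages = as.integer(take),
        ridge = fact$eps
      ))
    }
  }
  stop("feature covariance could not be factorized even with ridge; ",
       "use a larger image sample or a smaller feature dimension (d = ",
       d, ", n = ", take, ")")
}

#' Whiten a feature vector
#'
#' Computes `z = t(L) %*% (meanFeature - feature)`, so that
#' `sum(z^2)` equals the Mahalanobis form
#' `(fbar - f)' solve(sigma) (fbar - f)`. (With `sigma = I`, `z` is simply
#' `meanFeature - feature`.)
#'
#' @param feature numeric d-vector.
#' @param moments an [InvarianceMoments-class].
#' @return whitened d-vector.
#' @export
whitenFeature <- function(feature, moments) {
  stopifnot(is(moments, "InvarianceMoments"))
  if (length(feature) != length(moments@meanFeature))
    stop("feature dimension mismatch: got ", length(feature), ", expected ",
         length(moments@meanFeature))
  as.numeric(t(moments@L) %*% (moments@meanFeature - feature))
}

#' Construct a transformation family
#'
#' @param name family name.
#' @param params nonempty list of parameter values theta.
#' @param applyFun deterministic `function(image, theta)` returning a
#'   transformed image.
#' @return a [TransformFamily-class].
#' @export
transformFamily <- function(name, params, applyFun) {
  new("TransformFamily", name = name, params = params, applyFun = applyFun)
}

.flipH <- function(x) {
  if (length(dim(x)) == 3L) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  else x[, rev(seq_len(ncol(x))), drop = FALSE]
}

# exact 90-degree-multiple rotation (no interpolation)
.rot90k <- function(x, k) {
  rot1 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  rotm <- function(m) { for (i in seq_len(k %% 4)) m <- rot1(m); m }
  if (length(dim(x)) == 3L) {
    out <- NULL
    for (c in seq_len(dim(x)[3])) {
      r <- rotm(x[, , c])
      if (is.null(out)) out <- array(0, c(dim(r), dim(x)[3]))
      out[, , c] <- r
    }
    out
  } else {
    rotm(x)
  }
}

# numeric HSV -> RGB (avoids the quantizing hex-color round trip)
.hsv2rgbNum <- function(h, s, v) {
  hp <- (h %% 1) * 6
  c <- v * s
  x <- c * (1 - abs(hp %% 2 - 1))
  m <- v - c
  sector <- pmin(floor(hp), 5)
  r <- g <- b <- numeric(length(h))
  pick <- function(sec, a, bb, cc) {
    idx <- sector == sec
    r[idx] <<- a[idx]; g[idx] <<- bb[idx]; b[idx] <<- cc[idx]
  }
  zero <- numeric(length(h))
  pick(0, c, x, zero); pick(1, x, c, zero); pick(2, zero, c, x)
  pick(3, zero, x, c); pick(4, x, zero, c); pick(5, c, zero, x)
  cbind(r + m, g + m, b + m)
}

.shiftHue <- function(x, offset) {
  if (length(dim(x)) != 3L) return(x) # hue is undefined for single-channel
  d <- dim(x)
  r <- as.numeric(x[, , 1]); g <- as.numeric(x[, , 2]); b <- as.numeric(x[, , 3])
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 1)
  rgb <- .hsv2rgbNum(hsv[1, ] + offset, hsv[2, ], hsv[3, ])
  array(as.numeric(rgb), d)
}

#' Built-in transformation families
#'
#' `flipFamily()` applies a horizontal flip; `rotationFamily()` exact
#' 90/180/270-degree grid rotations (no interpolation artifacts);
#' `hueFamily()` hue rotations by the given offsets (fraction of a full hue
#' circle). The identity transform, which contributes a constant cosine of
#' 1, is excluded by default; `includeIdentity = TRUE` restores it.
#'
#' @param includeIdentity include the no-op transform in the family.
#' @param angles rotation angles in degrees (multiples of 90).
#' @param offsets hue offsets in `[0, 1)`.
#' @return a [TransformFamily-class].
#' @export
flipFamily <- function(includeIdentity = FALSE) {
  params <- if (includeIdentity) list(FALSE, TRUE) else list(TRUE)
  transformFamily("hflip", params,
                  function(x, theta) if (isTRUE(theta)) .flipH(x) else x)
}

#' @rdname flipFamily
#' @export
rotationFamily <- function(angles = c(90, 180, 270), includeIdentity = FALSE) {
  stopifnot(all(angles %% 90 == 0))
  params <- as.list(if (includeIdentity) c(0, angles) else angles)
  transformFamily("rotation", params,
                  function(x, theta) .rot90k(x, as.integer(theta / 90)))
}

#' @rdname flipFamily
#' @export
hueFamily <- function(offsets = c(1 / 3, 2 / 3), includeIdentity = FALSE) {
  params <- as.list(if (includeIdentity) c(0, offsets) else offsets)
  transformFamily("hue", params, .shiftHue)
}

.isStackedGrayscale <- function(px) {
  length(dim(px)) != 3L ||
    (identical(px[, , 1], px[, , 2]) && identical(px[, , 2], px[, , 3]))
}

.cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

#' Transformation-invariance score of an extractor on a dataset
#'
#' For `nEval` sampled images x and every parameter theta of the family,
#' computes the cosine similarity between the whitened clean feature
#' `z = t(L)(fbar - f(x))` and the whitened transformed feature
#' `z_theta = t(L)(fbar - f(t_theta(x)))`, and averages. A score near 1
#' means the features are invariant to the transformation; near 0, not at
#' all. Terms with a zero-norm whitened feature are skipped with a warning.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param dataset a [LabeledImageSet-class].
#' @param family a [TransformFamily-class].
#' @param moments an [InvarianceMoments-class] estimated for this extractor
#'   and dataset (see [estimateMoments()]).
#' @param nEval number of images averaged over (default 100).
#' @param seed integer seed for the image sample.
#' @return an [InvarianceResult-class].
#' @export
invarianceScore <- function(extractor, dataset, family, moments, nEval = 100L,
                            seed = 1L) {
  stopifnot(is(family, "TransformFamily"), is(moments, "InvarianceMoments"))
  n <- length(dataset)
  if (n == 0L) stop("dataset is empty")
  take <- min(n, nEval)
  idx <- withSeed(childSeed(seed, "inveval"), sample.int(n, take))
  imgs <- images(dataset)[idx]

  notes <- character(0)
  if (family@name == "hue" && all(vapply(imgs, .isStackedGrayscale, logical(1))))
    notes <- "hue transform is a no-op on single-channel or stacked-grayscale images"

  fClean <- embedDataset(extractor, imgs)$features
  cosines <- numeric(0)
  nSkipped <- 0L
  for (i in seq_len(take)) {
    z <- whitenFeature(fClean[i, ], moments)
    nz <- sqrt(sum(z^2))
    if (nz == 0) {
      nSkipped <- nSkipped + length(family@params)
      next
    }
    for (theta in family@params) {
      xt <- family@applyFun(imgs[[i]], theta)
      ft <- embedDataset(extractor, list(xt))$features[1, ]
      zt <- whitenFeature(ft, moments)
      nzt <- sqrt(sum(zt^2))
      if (nzt == 0) {
        nSkipped <- nSkipped + 1L
        next
      }
      cosines <- c(cosines, sum(z * zt) / (nz * nzt))
    }
  }
  if (nSkipped > 0L)
    warning(nSkipped, " term(s) skipped: whitened feature had zero norm")
  if (length(cosines) == 0L) stop("no valid terms to average")
  new("InvarianceResult",
    score = mean(cosines),
    family = family@name,
    nEval = as.integer(take),
    nSkipped = nSkipped,
    notes = notes
  )
}

#' Multi-view invariance score
#'
#' The multi-view variant replaces the transformed image by the second view
#' of the same object: the score is the mean cosine similarity between the
#' whitened features of the two views of each sampled pair. Groups without
#' exactly two views are excluded with a warning.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param dataset a [LabeledImageSet-class] with `groupId`/`viewId` pairing.
#' @param moments an [InvarianceMoments-class].
#' @param nEval number of pairs averaged over (default 100).
#' @param seed integer seed.
#' @return an [InvarianceResult-class] with family `"multiview"`.
#' @export
multiviewInvariance <- function(extractor, dataset, moments, nEval = 100L,
                                seed = 1L) {
  stopifnot(is(dataset, "LabeledImageSet"), is(moments, "InvarianceMoments"))
  gid <- groupIds(dataset)
  tab <- table(gid[!is.na(gid)])
  complete <- as.integer(names(tab)[tab == 2L])
  if (length(complete) == 0L) stop("dataset contains no complete view pairs")
  nBad <- sum(tab != 2L) + sum(is.na(gid))
  if (nBad > 0L)
    warning(nBad, " image(s)/group(s) without a complete pair excluded")

  take <- min(length(complete), nEval)
  pick <- withSeed(childSeed(seed, "mveval"),
                   complete[sample.int(length(complete), take)])
  imgs <- images(dataset)
  cosines <- numeric(0)
  nSkipped <- 0L
  for (g in pick) {
    rows <- which(gid == g)
    f1 <- embedDataset(extractor, imgs[rows[1]])$features[1, ]
    f2 <- embedDataset(extractor, imgs[rows[2]])$features[1, ]
    z1 <- whitenFeature(f1, moments)
    z2 <- whitenFeature(f2, moments)
    n1 <- sqrt(sum(z1^2)); n2 <- sqrt(sum(z2^2))
    if (n1 == 0 || n2 == 0) {
      nSkipped <- nSkipped + 1L
      next
    }
    cosines <- c(cosines, sum(z1 * z2) / (n1 * n2))
  }
  if (nSkipped > 0L)
    warning(nSkipped, " pair(s) skipped: whitened feature had zero norm")
  if (length(cosines) == 0L) stop("no valid pairs to average")
  new("InvarianceResult",
    score = mean(cosines),
    family = "multiview",
    nEval = as.integer(take),
    nSkipped = nSkipped,
    notes = character(0)
  )
}
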