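#' Construct a toy feature extractor with known analytic properties
#'
#' Toy extractors provide exact oracles for the evaluation stages:
#' \describe{
#'   \item{`random_projection`}{a fixed, seeded linear map of the flattened
#'     pixels (rows of a Gaussian matrix scaled by `1/sqrt(npix)`).}
#'   \item{`region_restricted`}{the same, but reading only pixels inside
#'     `region`; all other pixels are provably ignored (their columns of the
#'     linear map are zero).}
#'   \item{`flip_invariant`}{a seeded linear map applied to
#'     `(x + fliplr(x)) / 2`, invariant to horizontal flip by construction.}
#'   \item{`tiny_cnn`}{a small trainable network: 3x3 convolution (one filter
#'     per feature dimension), ReLU, global average pooling. Supports the
#'     finetuning protocol.}
#' }
#' All toys skip geometric preprocessing and normalization (they operate on
#' raw pixels), so analytic expectations hold exactly.
#'
#' @param kind one of "random_projection", "region_restricted",
#'   "flip_invariant", "tiny_cnn".
#' @param featureDim output dimensionality d >= 1.
#' @param seed RNG seed for the map / initial weights.
#' @param inputSize integer `(H, W)` or `(H, W, C)` the extractor expects.
#' @param region `(top, left, height, width)` for "region_restricted".
#' @return a [FeatureExtractor-class] (a [TrainableExtractor-class] for
#'   "tiny_cnn").
#' @examples
#' ex <- makeToyExtractor("random_projection", featureDim = 8, seed = 1,
#'                        inputSize = c(32, 32))
#' f <- embedImage(ex, matrix(runif(32 * 32), 32))
#' length(f)
#' @export
makeToyExtractor <- function(kind = c("random_projection", "region_restricted",
                                      "flip_invariant", "tiny_cnn"),
                             featureDim, seed = 1L, inputSize = c(224L, 224L),
                             region = NULL) {
  kind <- match.arg(kind)
  if (!isCount(featureDim, 1L)) stop("featureDim must be an integer >= 1")
  inputSize <- as.integer(inputSize)
  if (length(inputSize) == 2L) inputSize <- c(inputSize, 1L)
  H <- inputSize[1]; W <- inputSize[2]; C <- inputSize[3]
  npix <- H * W * C
  spec <- preprocessSpec(resizeSide = NA, cropSize = NA,
                         normalization = "none", stackChannels = FALSE)

  if (kind == "tiny_cnn") {
    return(.makeTinyCnn(featureDim, seed, inputSize, spec))
  }

  M <- withSeed(childSeed(seed, paste0("toy:", kind)),
                matrix(stats::rnorm(featureDim * npix), featureDim) / sqrt(npix))

  if (kind == "region_restricted") {
    if (is.null(region))
      stop("region_restricted extractor requires a region (top, left, height, width)")
    region <- as.integer(region)
    keep <- logical(npix)
    rows <- region[1]:(region[1] + region[3] - 1L)
    cols <- region[2]:(region[2] + region[4] - 1L)
    for (c in seq_len(C) - 1L) {
      for (j in cols) keep[c * H * W + (j - 1L) * H + rows] <- TRUE
    }
    M[, !keep] <- 0
  } else if (kind == "flip_invariant") {
    # equivalent linear map over pixels: column j of the image pairs with
    # column W + 1 - j (per channel)
    Msym <- M
    for (c in seq_len(C) - 1L) {
      for (j in seq_len(W)) {
        a <- c * H * W + (j - 1L) * H + seq_len(H)
        b <- c * H * W + (W - j) * H + seq_len(H)
        Msym[, a] <- (M[, a] + M[, b]) / 2
      }
    }
  }

  force(M)
  embedFun <- if (kind == "flip_invariant") {
    # symmetrize the image itself: embed(x) == embed(flip(x)) holds exactly
    # in floating point because elementwise (a + b) / 2 == (b + a) / 2
    function(px) {
      if (length(px) != ncol(M))
        stop("extractor expects ", ncol(M), " pixels, got ", length(px))
      flipped <- if (length(dim(px)) == 3L)
        px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
      else px[, rev(seq_len(ncol(px))), drop = FALSE]
      as.numeric(M %*% as.numeric((px + flipped) / 2))
    }
  } else {
    function(px) {
      v <- as.numeric(px)
      if (length(v) != ncol(M))
        stop("extractor expects ", ncol(M), " pixels, got ", length(v))
      as.numeric(M %*% v)
    }
  }

  new("FeatureExtractor",
    id = paste0(kind, "_d", featureDim, "_s", seed),
    featureDim = as.integer(featureDim),
    preprocess = spec,
    embedFun = embedFun,
    linearMap = if (kind == "flip_invariant") Msym else M,
    inputDim = inputSize,
    trainable = FALSE
  )
}

# --- tiny trainable CNN -----------------------------------------------------

# 3x3 "same" convolution (zero padding) implemented as a sum of shifted
# products; x is H x W, ker is 3 x 3.
.conv2dSame <- function(xpad, ker, H, W) {
  z <- matrix(0, H, W)
  for (u in 1:3) {
    for (v in 1:3) {
      z <- z + ker[u, v] * xpad[(u - 1) + seq_len(H), (v - 1) + seq_len(W)]
    }
  }
  z
}

.padZero <- function(x) {
  d <- dim(x)
  xp <- matrix(0, d[1] + 2L, d[2] + 2L)
  xp[2:(d[1] + 1L), 2:(d[2] + 1L)] <- x
  xp
}

.tinyCnnForward <- function(params, px) {
  x <- if (length(dim(px)) == 3L) apply(px, c(1, 2), mean) else px
  H <- nrow(x); W <- ncol(x)
  nf <- length(params$b)
  xpad <- .padZero(x)
  z <- array(0, c(H, W, nf))
  feat <- numeric(nf)
  for (f in seq_len(nf)) {
    zf <- .conv2dSame(xpad, params$W[, , f], H, W) + params$b[f]
    z[, , f] <- zf
    feat[f] <- mean(pmax(zf, 0))
  }
  list(feature = feat, cache = list(xpad = xpad, z = z, H = H, W = W))
}

.tinyCnnGrad <- function(params, px, cache, dFeature) {
  H <- cache$H; W <- cache$W
  nf <- length(params$b)
  dW <- array(0, dim(params$W))
  db <- numeric(nf)
  for (f in seq_len(nf)) {
    da <- (dFeature[f] / (H * W)) * (cache$z[, , f] > 0)
    db[f] <- sum(da)
    for (u in 1:3) {
      for (v in 1:3) {
        dW[u, v, f] <- sum(da * cache$xpad[(u - 1) + seq_len(H),
                                           (v - 1) + seq_len(W)])
      }
    }
  }
  list(W = dW, b = db)
}

.makeTinyCnn <- function(featureDim, seed, inputSize, spec) {
  params <- withSeed(childSeed(seed, "tinycnn"), {
    list(
      W = array(stats::rnorm(9 * featureDim, sd = 0.3), c(3, 3, featureDim)),
      b = numeric(featureDim)
    )
  })
  new("TrainableExtractor",
    id = paste0("tiny_cnn_d", featureDim, "_s", seed),
    featureDim = as.integer(featureDim),
    preprocess = spec,
    embedFun = function(px) stop("use embedImage() for trainable extractors"),
    linearMap = NULL,
    inputDim = inputSize,
    trainable = TRUE,
    params = params,
    forwardFun = .tinyCnnForward,
    gradFun = .tinyCnnGrad
  )
}

#' Embed a dataset with a feature extractor
#'
#' Applies the extractor's preprocessing and embedding to every image, in
#' order. When the extractor exposes a linear pixel map, embedding is done
#' as one matrix product.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param x a [LabeledImageSet-class] or a list of pixel arrays.
#' @return a list with `features` (an `n x d` matrix, row i the embedding of
#'   image i) and `labels` (integer vector, NA when `x` is a bare list).
#' @export
embedDataset <- function(extractor, x) {
  stopifnot(is(extractor, "FeatureExtractor"))
  imgs <- if (is(x, "LabeledImageSet")) images(x) else x
  labels <- if (is(x, "LabeledImageSet")) imageLabels(x)
            else rep(NA_integer_, length(imgs))
  d <- extractor@featureDim
  n <- length(imgs)
  if (n == 0L)
    return(list(features = matrix(numeric(0), 0, d), labels = integer(0)))

  pre <- vector("list", n)
  for (i in seq_len(n)) {
    pre[[i]] <- tryCatch(
      preprocessImage(imgs[[i]], extractor@preprocess),
      error = function(e) stop("preprocessing failed for image ", i, ": ",
                               conditionMessage(e))
    )
  }

  M <- extractor@linearMap
  if (!is.null(M) && all(vapply(pre, length, integer(1)) == ncol(M))) {
    Xflat <- matrix(unlist(pre, use.names = FALSE), nrow = n, byrow = TRUE)
    feats <- Xflat %*% t(M)
  } else {
    feats <- matrix(0, n, d)
    for (i in seq_len(n)) feats[i, ] <- embedImage(extractor, pre[[i]])
  }
  list(features = feats, labels = labels)
}
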